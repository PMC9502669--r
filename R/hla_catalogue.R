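#' HLA split-antigen catalogue
#'
#' The set of HLA split antigens screened when assessing donor-recipient
#' compatibility, grouped by locus (HLA-A, -B, -DR, -DQ). The default
#' catalogue holds the 50 split antigens most frequently typed in preparation
#' for kidney replacement therapy: 13 at HLA-A, 24 at HLA-B, 8 at HLA-DR and
#' 5 at HLA-DQ.
#'
#' @param groups Named list of character vectors, one per locus group
#'   (names `A`, `B`, `DR`, `DQ`). Defaults to the standard 50-antigen
#'   catalogue.
#' @return An object of class `kex_catalogue`: a list with elements
#'   `groups` (named list of antigen codes) and `total_size`.
#' @examples
#' cat50 <- kex_catalogue()
#' cat50$total_size # 50
#' @export
kex_catalogue <- function(groups = kex_default_antigens()) {
  stopifnot(is.list(groups))
  if (!identical(sort(names(groups)), sort(c("A", "B", "DR", "DQ")))) {
    stop("catalogue must have exactly the locus groups A, B, DR, DQ",
         call. = FALSE)
  }
  groups <- groups[c("A", "B", "DR", "DQ")]
  codes <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(codes)) {
    stop("duplicate antigen codes in catalogue: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(groups = groups, total_size = length(codes)),
    class = "kex_catalogue"
  )
}

#' @rdname kex_catalogue
#' @export
kex_default_antigens <- function() {
  list(
    A  = c("A23", "A24", "A25", "A26", "A29", "A31", "A32", "A33", "A34",
           "A66", "A68", "A69", "A74"),
    B  = c("B38", "B39", "B44", "B45", "B49", "B50", "B51", "B52", "B54",
           "B55", "B56", "B57", "B58", "B60", "B61", "B62", "B63", "B64",
           "B65", "B71", "B72", "B75", "B76", "B77"),
    DR = c("DR11", "DR12", "DR13", "DR14", "DR15", "DR16", "DR17", "DR18"),
    DQ = c("DQ5", "DQ6", "DQ7", "DQ8", "DQ9")
  )
}

#' @export
print.kex_catalogue <- function(x, ...) {
  cat("<kex_catalogue> ", x$total_size, " antigens (",
      paste(sprintf("%s: %d", names(x$groups), lengths(x$groups)),
            collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# All codes as a flat character vector, in catalogue order.
catalogue_codes <- function(catalogue) {
  unlist(catalogue$groups, use.names = FALSE)
}

# Validate a set of antigen codes against the catalogue; names unknown codes.
assert_codes <- function(codes, catalogue, what = "antigen") {
  bad <- setdiff(codes, catalogue_codes(catalogue))
  if (length(bad) > 0) {
    stop("unknown ", what, " code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(codes)
}
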