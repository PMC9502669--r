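#' Read and write cohorts as JSON
#'
#' Cohort files are JSON objects with a `pairs` array; each pair has
#' `pair_id`, a `donor` object (`hla` with arrays `A`, `B`, `DR`, `DQ`,
#' plus `abo`, `age`, `sex`, `weight_kg`) and a `recipient` object with the
#' same fields plus `antibodies`. A missing `antibodies` field defaults to
#' the empty set with a warning. Writing then reading a cohort is the
#' identity.
#'
#' @param path File path.
#' @param cohort A cohort tibble.
#' @param catalogue A [kex_catalogue()] used for validation.
#' @return `read_cohort()`: a validated cohort tibble. `write_cohort()`:
#'   the path, invisibly.
#' @export
read_cohort <- function(path, catalogue = kex_catalogue()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$pairs)) {
    stop("cohort JSON must have a top-level 'pairs' array", call. = FALSE)
  }
  rows <- purrr::imap(raw$pairs, function(p, idx) {
    where <- paste0("pairs[", idx, "]")
    need <- function(obj, field, ctx) {
      if (is.null(obj[[field]])) {
        stop("missing field '", field, "' in ", ctx, call. = FALSE)
      }
      obj[[field]]
    }
    pid <- need(p, "pair_id", where)
    d <- need(p, "donor", where)
    r <- need(p, "recipient", where)
    parse_hla <- function(person, ctx) {
      h <- need(person, "hla", ctx)
      purrr::map(
        stats::setNames(c("A", "B", "DR", "DQ"), c("A", "B", "DR", "DQ")),
        ~ as.character(unlist(h[[.x]]))
      )
    }
    ab <- r$antibodies
    if (is.null(ab)) {
      warning("missing 'antibodies' in ", where,
              ".recipient; defaulting to empty set", call. = FALSE)
      ab <- character()
    }
    tibble::tibble(
      pair_id = as.integer(pid),
      donor_hla = list(parse_hla(d, paste0(where, ".donor"))),
      donor_abo = as.character(need(d, "abo", where)),
      donor_age = as.integer(need(d, "age", where)),
      donor_sex = as.character(need(d, "sex", where)),
      donor_weight_kg = as.numeric(need(d, "weight_kg", where)),
      recipient_hla = list(parse_hla(r, paste0(where, ".recipient"))),
      recipient_abo = as.character(need(r, "abo", where)),
      recipient_age = as.integer(need(r, "age", where)),
      recipient_sex = as.character(need(r, "sex", where)),
      recipient_weight_kg = as.numeric(need(r, "weight_kg", where)),
      recipient_antibodies = list(as.character(unlist(ab)))
    )
  })
  validate_cohort(dplyr::bind_rows(rows), catalogue)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path, catalogue = kex_catalogue()) {
  cohort <- validate_cohort(cohort, catalogue)
  pairs <- purrr::map(seq_len(nrow(cohort)), function(i) {
    list(
      pair_id = cohort$pair_id[i],
      donor = list(
        hla = purrr::map(cohort$donor_hla[[i]], as.character),
        abo = cohort$donor_abo[i], age = cohort$donor_age[i],
        sex = cohort$donor_sex[i], weight_kg = cohort$donor_weight_kg[i]
      ),
      recipient = list(
        hla = purrr::map(cohort$recipient_hla[[i]], as.character),
        abo = cohort$recipient_abo[i], age = cohort$recipient_age[i],
        sex = cohort$recipient_sex[i],
        weight_kg = cohort$recipient_weight_kg[i],
        antibodies = as.character(cohort$recipient_antibodies[[i]])
      )
    )
  })
  jsonlite::write_json(list(pairs = pairs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate a cohort tibble
#'
#' Checks pair ids (contiguous, 0-based, unique), antigen and antibody
#' codes against the catalogue, locus-group caps, blood groups, sexes and
#' positive ages/weights. Errors name the offending field and pair.
#'
#' @param cohort A cohort tibble.
#' @param catalogue A [kex_catalogue()].
#' @return The cohort, invisibly validated (returned ordered by `pair_id`).
#' @export
validate_cohort <- function(cohort, catalogue = kex_catalogue()) {
  req <- c("pair_id", "donor_hla", "donor_abo", "donor_age", "donor_sex",
           "donor_weight_kg", "recipient_hla", "recipient_abo",
           "recipient_age", "recipient_sex", "recipient_weight_kg",
           "recipient_antibodies")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  if (n < 2) stop("a cohort needs at least 2 pairs", call. = FALSE)
  if (!setequal(cohort$pair_id, 0:(n - 1)) ||
      anyDuplicated(cohort$pair_id)) {
    stop("pair_id values must be exactly 0..", n - 1, call. = FALSE)
  }
  cohort <- dplyr::arrange(cohort, .data$pair_id)
  for (i in seq_len(n)) {
    ctx <- paste0("pair ", cohort$pair_id[i])
    tryCatch({
      validate_hla(cohort$donor_hla[[i]], catalogue)
      validate_hla(cohort$recipient_hla[[i]], catalogue)
      assert_codes(cohort$recipient_antibodies[[i]], catalogue, "antibody")
    }, error = function(e) {
      stop(conditionMessage(e), " (", ctx, ")", call. = FALSE)
    })
    if (!cohort$donor_abo[i] %in% c("O", "A", "B", "AB") ||
        !cohort$recipient_abo[i] %in% c("O", "A", "B", "AB")) {
      stop("invalid blood group in ", ctx, call. = FALSE)
    }
    if (!cohort$donor_sex[i] %in% c("M", "F") ||
        !cohort$recipient_sex[i] %in% c("M", "F")) {
      stop("invalid sex in ", ctx, call. = FALSE)
    }
    if (cohort$donor_age[i] <= 0 || cohort$recipient_age[i] <= 0 ||
        cohort$donor_weight_kg[i] <= 0 ||
        cohort$recipient_weight_kg[i] <= 0) {
      stop("ages and weights must be positive in ", ctx, call. = FALSE)
    }
  }
  cohort
}

#' Export the compatibility matrix as CSV
#'
#' Writes the weighted adjacency matrix with a header row of pair ids and
#' integer cells.
#'
#' @param g A `kex_graph`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_graph_csv <- function(g, path) {
  stopifnot(inherits(g, "kex_graph"))
  utils::write.csv(as.data.frame(g$weights), path, row.names = FALSE)
  invisible(path)
}

#' Write a solution as JSON
#'
#' Serialises `{total_weight, cycles: [{vertices, weight}]}`.
#'
#' @param solution A `kex_solution`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_solution_json <- function(solution, path) {
  out <- list(
    total_weight = solution$total_weight,
    cycles = purrr::map(seq_len(nrow(solution$cycles)), function(i) {
      list(vertices = solution$cycles$vertices[[i]],
           weight = solution$cycles$weight[i])
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
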