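#' Criterion weights and score tables
#'
#' Configuration of the match-quality model. Five weighted criteria (HLA
#' mismatch quality, ABO compatibility, age pairing, sex pairing, weight
#' pairing) contribute `score * weight` each to an edge; a `baseline` is added
#' to every crossmatch-compatible edge so that compatible edges always carry a
#' strictly positive weight. The sixth criterion, the HLA crossmatch, is a
#' hard gate: a positive crossmatch forces edge weight 0.
#'
#' All scores and weights are non-negative integers, which keeps the
#' arithmetic exact on the mod-2^ell secret-sharing backend. The score tables
#' are constrained only by the ordinal clinical orderings:
#' * `bins_hla` (counts 0, 1-2, 3-4, >=5 mismatches) non-increasing;
#' * `scores_age`: same category >= junior donor to senior recipient >=
#'   senior donor to junior recipient;
#' * `scores_sex`: same sex >= male-to-female >= female-to-male;
#' * `scores_abo` and `scores_weight`: compatible/heavier-donor score >= other.
#'
#' @param w Named integer vector of criterion weights
#'   (`hla_quality`, `abo`, `age`, `sex`, `weight`).
#' @param baseline Non-negative integer added to every compatible edge.
#' @param bins_hla Length-4 scores for 0, 1-2, 3-4 and >=5 mismatches.
#' @param scores_abo Length-2 scores `c(compatible, incompatible)`.
#' @param scores_age Length-3 scores `c(same_category, junior_to_senior,
#'   senior_to_junior)`.
#' @param scores_sex Length-3 scores `c(same_sex, male_to_female,
#'   female_to_male)`.
#' @param scores_weight Length-2 scores `c(donor_not_lighter, donor_lighter)`.
#' @param weight_margin_kg Donor may be this many kg lighter than the
#'   recipient and still receive the favourable weight score.
#' @param senior_age Age (years) at and above which a person counts as senior.
#' @return An object of class `kex_weights` (a named list).
#' @examples
#' cfg <- kex_weights()
#' cfg$bins_hla
#' @export
kex_weights <- function(w = c(hla_quality = 1L, abo = 1L, age = 1L,
                              sex = 1L, weight = 1L),
                        baseline = 1L,
                        bins_hla = c(3L, 2L, 1L, 0L),
                        scores_abo = c(1L, 0L),
                        scores_age = c(2L, 1L, 0L),
                        scores_sex = c(2L, 1L, 0L),
                        scores_weight = c(1L, 0L),
                        weight_margin_kg = 0,
                        senior_age = 55L) {
  crit <- c("hla_quality", "abo", "age", "sex", "weight")
  if (!all(crit %in% names(w))) {
    stop("w must name all five criteria: ", paste(crit, collapse = ", "),
         call. = FALSE)
  }
  w <- as.integer(w[crit])
  chk_nonneg <- function(x, nm) {
    if (any(x < 0) || any(x != floor(x))) {
      stop(nm, " must be non-negative integers", call. = FALSE)
    }
  }
  chk_nonneg(w, "w"); chk_nonneg(baseline, "baseline")
  chk_nonneg(bins_hla, "bins_hla"); chk_nonneg(scores_abo, "scores_abo")
  chk_nonneg(scores_age, "scores_age"); chk_nonneg(scores_sex, "scores_sex")
  chk_nonneg(scores_weight, "scores_weight")
  if (is.unsorted(rev(bins_hla))) {
    stop("bins_hla must be non-increasing from the 0-mismatch bin",
         call. = FALSE)
  }
  if (is.unsorted(rev(scores_age)) || is.unsorted(rev(scores_sex))) {
    stop("scores_age and scores_sex must respect their ordinal orderings",
         call. = FALSE)
  }
  if (scores_abo[1] < scores_abo[2] || scores_weight[1] < scores_weight[2]) {
    stop("favourable score must be >= unfavourable score", call. = FALSE)
  }
  structure(
    list(
      w = w, baseline = as.integer(baseline),
      bins_hla = as.integer(bins_hla),
      scores_abo = as.integer(scores_abo),
      scores_age = as.integer(scores_age),
      scores_sex = as.integer(scores_sex),
      scores_weight = as.integer(scores_weight),
      weight_margin_kg = weight_margin_kg,
      senior_age = as.integer(senior_age)
    ),
    class = "kex_weights"
  )
}

#' @export
print.kex_weights <- function(x, ...) {
  cat("<kex_weights> w = [",
      paste(sprintf("%s=%d", names(x$w), x$w), collapse = ", "),
      "], baseline =", x$baseline, "\n")
  invisible(x)
}

# Largest edge weight attainable under a configuration; used for ring
# overflow bounds on the secret-sharing backend.
max_edge_weight <- function(cfg) {
  cfg$baseline + sum(cfg$w * c(max(cfg$bins_hla), max(cfg$scores_abo),
                               max(cfg$scores_age), max(cfg$scores_sex),
                               max(cfg$scores_weight)))
}
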