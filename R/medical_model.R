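#' HLA crossmatch
#'
#' Virtual crossmatch between a donor's HLA antigens and a recipient's
#' anti-HLA antibody panel. The pair is immunologically compatible if and
#' only if none of the donor's antigens is targeted by a recipient antibody;
#' a single antigen-antibody hit excludes the transplant outright.
#'
#' @param donor_antigens Character vector of the donor's antigen codes
#'   (across all locus groups).
#' @param recipient_antibodies Character vector of antigen codes the
#'   recipient holds antibodies against.
#' @param catalogue A [kex_catalogue()].
#' @return `TRUE` if compatible (no hit), `FALSE` otherwise.
#' @examples
#' hla_crossmatch(c("A23", "B44"), c("B45", "DQ9")) # TRUE
#' hla_crossmatch("A24", "A24")                     # FALSE
#' @export
hla_crossmatch <- function(donor_antigens, recipient_antibodies,
                           catalogue = kex_catalogue()) {
  assert_codes(donor_antigens, catalogue, "antigen")
  assert_codes(recipient_antibodies, catalogue, "antibody")
  length(intersect(donor_antigens, recipient_antibodies)) == 0L
}

#' HLA mismatch count
#'
#' Counts, per locus group, the distinct donor antigens absent from the
#' recipient's own antigen set, and sums over the four groups. As each person
#' carries at most two antigens per group, at most two mismatches can occur
#' per group, for a total in 0..8. A donor whose antigens are a subset of the
#' recipient's at every group has zero mismatches (rare outside twin pairs).
#'
#' @param donor_hla,recipient_hla Named lists (`A`, `B`, `DR`, `DQ`) of
#'   character vectors with at most 2 antigens per group.
#' @inheritParams hla_crossmatch
#' @return Integer in 0..8.
#' @export
hla_mismatch_count <- function(donor_hla, recipient_hla,
                               catalogue = kex_catalogue()) {
  validate_hla(donor_hla, catalogue)
  validate_hla(recipient_hla, catalogue)
  counts <- vapply(names(catalogue$groups), function(g) {
    d <- unique(donor_hla[[g]] %||% character())
    r <- recipient_hla[[g]] %||% character()
    min(length(setdiff(d, r)), 2L)
  }, integer(1))
  sum(counts)
}

validate_hla <- function(hla, catalogue) {
  if (!is.list(hla)) stop("HLA profile must be a named list", call. = FALSE)
  extra <- setdiff(names(hla), names(catalogue$groups))
  if (length(extra) > 0) {
    stop("unknown locus group(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (g in names(hla)) {
    assert_codes(hla[[g]], catalogue, "antigen")
    if (length(unique(hla[[g]])) > 2) {
      stop("more than 2 antigens in group ", g, call. = FALSE)
    }
    if (!all(hla[[g]] %in% catalogue$groups[[g]])) {
      stop("antigen(s) ",
           paste(setdiff(hla[[g]], catalogue$groups[[g]]), collapse = ", "),
           " do not belong to locus group ", g, call. = FALSE)
    }
  }
  invisible(hla)
}

#' HLA mismatch bin score
#'
#' Maps a mismatch count to its configured bin score. Mismatch impact is
#' categorised in four bins: no mismatch; 1-2 mismatches; 3-4 mismatches;
#' and 5 or more, the worst category. A count of exactly 5 falls in the worst
#' bin (the published category boundaries leave 5 between "3-4" and "more
#' than 5"; this implementation closes the gap with >=5 = worst).
#'
#' @param count Integer mismatch count in 0..8.
#' @param cfg A [kex_weights()] configuration.
#' @return The bin score, non-increasing in `count`.
#' @export
hla_mismatch_score <- function(count, cfg = kex_weights()) {
  if (any(count < 0 | count > 8)) {
    stop("mismatch count must lie in 0..8", call. = FALSE)
  }
  bin <- findInterval(count, c(0, 1, 3, 5))
  cfg$bins_hla[bin]
}

#' ABO blood-group compatibility and score
#'
#' Donor-to-recipient blood group compatibility: O donates to everyone,
#' A to A/AB, B to B/AB, AB only to AB. ABO incompatibility is a score
#' penalty rather than a hard exclusion (graft pre-processing makes
#' ABO-incompatible transplants possible, at elevated first-year risk);
#' only the HLA crossmatch excludes.
#'
#' @param donor_abo,recipient_abo Blood groups, one of `"O"`, `"A"`, `"B"`,
#'   `"AB"`.
#' @inheritParams hla_mismatch_score
#' @return `abo_compatible()`: logical. `abo_score()`: integer score.
#' @export
abo_compatible <- function(donor_abo, recipient_abo) {
  ok <- c("O", "A", "B", "AB")
  if (!donor_abo %in% ok || !recipient_abo %in% ok) {
    stop("blood group must be one of O, A, B, AB", call. = FALSE)
  }
  can_donate_to <- list(
    O  = c("O", "A", "B", "AB"),
    A  = c("A", "AB"),
    B  = c("B", "AB"),
    AB = "AB"
  )
  recipient_abo %in% can_donate_to[[donor_abo]]
}

#' @rdname abo_compatible
#' @export
abo_score <- function(donor_abo, recipient_abo, cfg = kex_weights()) {
  if (abo_compatible(donor_abo, recipient_abo)) cfg$scores_abo[1]
  else cfg$scores_abo[2]
}

#' Age-pairing score
#'
#' Participants are categorised as junior (below `senior_age`, default 55) or
#' senior. Outcomes order: same category best, junior donor to senior
#' recipient next, senior donor to junior recipient worst. Age exactly at the
#' cutoff counts as senior.
#'
#' @param donor_age,recipient_age Ages in years.
#' @inheritParams hla_mismatch_score
#' @return Integer score.
#' @export
age_score <- function(donor_age, recipient_age, cfg = kex_weights()) {
  stopifnot(donor_age > 0, recipient_age > 0)
  ds <- donor_age >= cfg$senior_age
  rs <- recipient_age >= cfg$senior_age
  if (ds == rs) cfg$scores_age[1]
  else if (!ds && rs) cfg$scores_age[2]
  else cfg$scores_age[3]
}

#' Sex-pairing score
#'
#' Allograft survival orders same-sex pairs best, male donor to female
#' recipient next, and female donor to male recipient worst.
#'
#' @param donor_sex,recipient_sex `"M"` or `"F"`.
#' @inheritParams hla_mismatch_score
#' @return Integer score.
#' @export
sex_score <- function(donor_sex, recipient_sex, cfg = kex_weights()) {
  if (!donor_sex %in% c("M", "F") || !recipient_sex %in% c("M", "F")) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  if (donor_sex == recipient_sex) cfg$scores_sex[1]
  else if (donor_sex == "M") cfg$scores_sex[2]
  else cfg$scores_sex[3]
}

#' Weight-pairing score
#'
#' Recipients of kidneys from lighter donors face higher allograft-loss risk
#' (a lighter donor's kidney may not support a heavier recipient's body
#' functions). The favourable score applies when the donor is not lighter
#' than the recipient, up to the configured margin.
#'
#' @param donor_weight,recipient_weight Body weights in kg.
#' @inheritParams hla_mismatch_score
#' @return Integer score.
#' @export
weight_score <- function(donor_weight, recipient_weight, cfg = kex_weights()) {
  stopifnot(donor_weight > 0, recipient_weight > 0)
  if (donor_weight >= recipient_weight - cfg$weight_margin_kg) {
    cfg$scores_weight[1]
  } else {
    cfg$scores_weight[2]
  }
}

#' Per-pair criterion scores
#'
#' Evaluates the five weighted criteria and the crossmatch gate for one
#' ordered donor-recipient combination.
#'
#' @param donor,recipient Profile lists as stored in a cohort row: the donor
#'   has `hla`, `abo`, `age`, `sex`, `weight_kg`; the recipient additionally
#'   has `antibodies`.
#' @inheritParams hla_mismatch_score
#' @param catalogue A [kex_catalogue()].
#' @return Named list with integer vector `scores` (hla_quality, abo, age,
#'   sex, weight) and logical `crossmatch`.
#' @export
criterion_scores <- function(donor, recipient, cfg = kex_weights(),
                             catalogue = kex_catalogue()) {
  xm <- hla_crossmatch(unlist(donor$hla, use.names = FALSE),
                       recipient$antibodies %||% character(), catalogue)
  mm <- hla_mismatch_count(donor$hla, recipient$hla, catalogue)
  scores <- c(
    hla_quality = hla_mismatch_score(mm, cfg),
    abo    = abo_score(donor$abo, recipient$abo, cfg),
    age    = age_score(donor$age, recipient$age, cfg),
    sex    = sex_score(donor$sex, recipient$sex, cfg),
    weight = weight_score(donor$weight_kg, recipient$weight_kg, cfg)
  )
  list(scores = scores, crossmatch = xm)
}

#' Edge weight of an ordered donor-recipient combination
#'
#' The compatibility-graph edge weight: 0 if the HLA crossmatch fails;
#' otherwise `baseline + sum(score * weight)` over the five criteria (the
#' dot product of the criterion score vector with the configured weights).
#'
#' @inheritParams criterion_scores
#' @return Non-negative integer weight.
#' @examples
#' d <- list(hla = list(A = "A23"), abo = "O", age = 40, sex = "M",
#'           weight_kg = 80)
#' r <- list(hla = list(A = "A24"), antibodies = character(), abo = "A",
#'           age = 45, sex = "M", weight_kg = 70)
#' edge_weight(d, r)
#' @export
edge_weight <- function(donor, recipient, cfg = kex_weights(),
                        catalogue = kex_catalogue()) {
  cs <- criterion_scores(donor, recipient, cfg, catalogue)
  if (!cs$crossmatch) return(0L)
  as.integer(cfg$baseline + sum(cs$scores * cfg$w))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
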