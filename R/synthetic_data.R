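#' Generate a synthetic donor-recipient cohort
#'
#' Seeded generator of incompatible donor-recipient pairs with the
#' statistical structure the matching pipeline assumes. Per person, two
#' antigens per locus group are drawn uniformly with replacement from the
#' catalogue and deduplicated (homozygosity allowed). The recipient's
#' anti-HLA antibody panel draws each catalogue antigen independently with
#' probability `pra` (panel-reactive antibody fraction), excluding the
#' recipient's own antigens. Blood groups follow `abo_freqs`; ages are
#' uniform over `age_range`; weights are normal, truncated to
#' `weight_range`; sex is Bernoulli(`sex_prob_male`).
#'
#' The defaults (PRA 0.10; ABO frequencies 0.43/0.40/0.12/0.05 for O/A/B/AB;
#' ages 18-75; weight 80 +/- 15 kg on 40-150 kg) are plausible European-pool
#' placeholders, configurable because the model publishes no cohort
#' statistics of its own.
#'
#' @param n_pairs Number of donor-recipient pairs (vertices), >= 2.
#' @param seed Integer seed; the cohort is fully deterministic given it.
#' @param pra Probability a recipient holds an antibody against any given
#'   catalogue antigen.
#' @param abo_freqs Named probabilities for O, A, B, AB; must sum to 1.
#' @param age_range Two integers, inclusive uniform range in years.
#' @param weight_mean,weight_sd,weight_range Truncated-normal weight model
#'   in kg.
#' @param sex_prob_male Probability of male sex.
#' @param catalogue A [kex_catalogue()].
#' @return A cohort tibble, one row per pair: `pair_id` (0-based),
#'   `donor_hla`, `donor_abo`, `donor_age`, `donor_sex`, `donor_weight_kg`,
#'   and the same for the recipient plus `recipient_antibodies`.
#' @examples
#' cohort <- generate_cohort(4, seed = 1)
#' cohort$pair_id
#' @export
generate_cohort <- function(n_pairs, seed,
                            pra = 0.10,
                            abo_freqs = c(O = 0.43, A = 0.40, B = 0.12,
                                          AB = 0.05),
                            age_range = c(18L, 75L),
                            weight_mean = 80, weight_sd = 15,
                            weight_range = c(40, 150),
                            sex_prob_male = 0.5,
                            catalogue = kex_catalogue()) {
  if (n_pairs < 2) stop("n_pairs must be >= 2", call. = FALSE)
  if (pra < 0 || pra > 1) stop("pra must lie in [0, 1]", call. = FALSE)
  if (!all(c("O", "A", "B", "AB") %in% names(abo_freqs)) ||
      abs(sum(abo_freqs) - 1) > 1e-9) {
    stop("abo_freqs must name O, A, B, AB and sum to 1", call. = FALSE)
  }
  codes <- catalogue_codes(catalogue)
  with_local_seed(seed, {
    person <- function(with_antibodies) {
      hla <- purrr::map(catalogue$groups,
                        ~ unique(sample(.x, 2, replace = TRUE)))
      own <- unlist(hla, use.names = FALSE)
      p <- list(
        hla = hla,
        abo = sample(c("O", "A", "B", "AB"), 1,
                     prob = abo_freqs[c("O", "A", "B", "AB")]),
        age = sample(age_range[1]:age_range[2], 1),
        sex = if (stats::runif(1) < sex_prob_male) "M" else "F",
        weight_kg = round(min(max(stats::rnorm(1, weight_mean, weight_sd),
                                  weight_range[1]), weight_range[2]), 1)
      )
      if (with_antibodies) {
        hit <- stats::runif(length(codes)) < pra
        p$antibodies <- setdiff(codes[hit], own)
      }
      p
    }
    rows <- purrr::map(seq_len(n_pairs), function(i) {
      d <- person(FALSE)
      r <- person(TRUE)
      tibble::tibble(
        pair_id = i - 1L,
        donor_hla = list(d$hla), donor_abo = d$abo, donor_age = d$age,
        donor_sex = d$sex, donor_weight_kg = d$weight_kg,
        recipient_hla = list(r$hla), recipient_abo = r$abo,
        recipient_age = r$age, recipient_sex = r$sex,
        recipient_weight_kg = r$weight_kg,
        recipient_antibodies = list(r$antibodies)
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Run code under a fixed seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Hand-constructed cohorts with known graph topology
#'
#' Small engineered cohorts realising fixed topologies for golden tests:
#' * `two_cycle`: 2 pairs compatible in both directions (one 2-cycle);
#' * `triangle`: 3 pairs forming the single directed 3-cycle 0 -> 1 -> 2 -> 0;
#' * `star_conflict`: 4 pairs where the heaviest 2-cycle conflicts with two
#'   lighter disjoint 2-cycles whose combined weight beats it;
#' * `no_match`: 2 pairs with mutual antigen-antibody hits (empty graph).
#'
#' @param name Fixture name.
#' @return A cohort tibble.
#' @export
engineered_fixture <- function(name) {
  base_person <- function(a1, a2, abo = "O", age = 40, sex = "M", wt = 80,
                          antibodies = NULL) {
    p <- list(hla = list(A = a1, B = character(), DR = character(),
                         DQ = a2),
              abo = abo, age = age, sex = sex, weight_kg = wt)
    if (!is.null(antibodies)) p$antibodies <- antibodies
    p
  }
  pair_row <- function(id, d, r) {
    tibble::tibble(
      pair_id = id,
      donor_hla = list(d$hla), donor_abo = d$abo, donor_age = d$age,
      donor_sex = d$sex, donor_weight_kg = d$weight_kg,
      recipient_hla = list(r$hla), recipient_abo = r$abo,
      recipient_age = r$age, recipient_sex = r$sex,
      recipient_weight_kg = r$weight_kg,
      recipient_antibodies = list(r$antibodies %||% character())
    )
  }
  fixtures <- c("two_cycle", "triangle", "star_conflict", "no_match")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  switch(
    name,
    two_cycle = dplyr::bind_rows(
      pair_row(0L, base_person("A23", "DQ5"),
               base_person("A24", "DQ6", antibodies = "A23")),
      pair_row(1L, base_person("A25", "DQ7"),
               base_person("A26", "DQ8", antibodies = "A25"))
    ),
    triangle = {
      # donor i blocked by own recipient's antibodies, accepted by next
      d <- list(base_person("A23", "DQ5"), base_person("A24", "DQ6"),
                base_person("A25", "DQ7"))
      r <- list(
        base_person("A26", "DQ8", age = 60, antibodies = c("A23", "A24")),
        base_person("A29", "DQ9", sex = "F", antibodies = c("A24", "A25")),
        base_person("A31", "DQ5", wt = 95, antibodies = c("A25", "A23"))
      )
      # edges 0->1, 1->2, 2->0 only
      dplyr::bind_rows(
        pair_row(0L, d[[1]], r[[1]]),
        pair_row(1L, d[[2]], r[[2]]),
        pair_row(2L, d[[3]], r[[3]])
      )
    },
    star_conflict = {
      # all four donors broadly acceptable except where antibodies forbid;
      # antibody panels leave 2-cycles (0,1), (0,2)... engineered below so
      # that (1,2) is heaviest but conflicts with disjoint (0,1) and (2,3)
      p0 <- base_person("A23", "DQ5")
      p1 <- base_person("A24", "DQ6", abo = "O", age = 40)
      p2 <- base_person("A25", "DQ7", abo = "O", age = 40)
      p3 <- base_person("A26", "DQ8")
      r0 <- base_person("A23", "DQ5", abo = "A", age = 70, sex = "F",
                        antibodies = c("A25", "A26"))
      r1 <- base_person("A24", "DQ6", abo = "O", age = 40,
                        antibodies = "A26")
      r2 <- base_person("A25", "DQ7", abo = "O", age = 40,
                        antibodies = "A23")
      r3 <- base_person("A26", "DQ8", abo = "B", age = 70, sex = "F",
                        antibodies = c("A23", "A24"))
      dplyr::bind_rows(
        pair_row(0L, p0, r0), pair_row(1L, p1, r1),
        pair_row(2L, p2, r2), pair_row(3L, p3, r3)
      )
    },
    no_match = dplyr::bind_rows(
      pair_row(0L, base_person("A23", "DQ5"),
               base_person("A24", "DQ6", antibodies = c("A23", "A25"))),
      pair_row(1L, base_person("A25", "DQ7"),
               base_person("A26", "DQ8", antibodies = c("A25", "A23")))
    )
  )
}
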