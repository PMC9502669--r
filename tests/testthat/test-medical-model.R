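test_that("default catalogue holds the 50 standard split antigens", {
  cat50 <- kex_catalogue()
  expect_equal(cat50$total_size, 50)
  expect_equal(lengths(cat50$groups), c(A = 13, B = 24, DR = 8, DQ = 5))
  codes <- unlist(cat50$groups, use.names = FALSE)
  expect_equal(anyDuplicated(codes), 0)
  expect_error(kex_catalogue(list(A = c("A23", "A23"), B = "B38",
                                  DR = "DR11", DQ = "DQ5")),
               "duplicate")
})

test_that("crossmatch is the empty-intersection test and rejects unknown codes", {
  expect_false(hla_crossmatch("A24", "A24"))
  expect_true(hla_crossmatch(c("A23", "B44", "DR11", "DQ5"), character()))
  expect_true(hla_crossmatch(c("A23", "B44"), c("B45", "DQ9")))
  expect_error(hla_crossmatch("A99", character()), "A99")
  expect_error(hla_crossmatch("A23", "B999"), "B999")
})

test_that("crossmatch agrees with a brute-force catalogue scan on random profiles", {
  cat50 <- kex_catalogue()
  codes <- unlist(cat50$groups, use.names = FALSE)
  for (s in 1:1000) {
    p <- rand_profiles(s)
    # SIMD-style scan: per-antigen hit indicator, OR-reduced, inverted
    hits <- vapply(codes, function(a) {
      (a %in% p$donor) && (a %in% p$antibodies)
    }, logical(1))
    expect_identical(hla_crossmatch(p$donor, p$antibodies), !any(hits))
  }
})

test_that("mismatch counting is per-group, distinct, capped at two", {
  cat50 <- kex_catalogue()
  subset_prof <- list(A = c("A23", "A24"), B = "B38", DR = "DR11",
                      DQ = "DQ5")
  expect_equal(hla_mismatch_count(subset_prof, subset_prof), 0)
  expect_equal(hla_mismatch_count(
    list(A = c("A23", "A24")),
    list(A = c("A25", "A26"), B = "B38", DR = "DR11", DQ = "DQ5")), 2)
  donor <- list(A = c("A23", "A24"), B = c("B38", "B39"),
                DR = c("DR11", "DR12"), DQ = c("DQ5", "DQ6"))
  recip <- list(A = c("A25", "A26"), B = c("B44", "B45"),
                DR = c("DR13", "DR14"), DQ = c("DQ7", "DQ8"))
  expect_equal(hla_mismatch_count(donor, recip), 8)
  # homozygous donor contributes at most one mismatch in its group
  expect_equal(hla_mismatch_count(list(A = c("A23", "A23")),
                                  list(A = "A24")), 1)
  expect_error(validate_hla(list(A = c("A23", "A24", "A25")), cat50),
               "more than 2")
  expect_error(hla_mismatch_count(list(A = "B38"), recip),
               "locus group")
})

test_that("mismatch bins map 0 / 1-2 / 3-4 / >=5 with count 5 in the worst bin", {
  expect_equal(hla_mismatch_score(0), 3)
  expect_equal(hla_mismatch_score(1), 2)
  expect_equal(hla_mismatch_score(2), 2)
  expect_equal(hla_mismatch_score(3), 1)
  expect_equal(hla_mismatch_score(4), 1)
  expect_equal(hla_mismatch_score(5), 0)
  expect_equal(hla_mismatch_score(7), 0)
  expect_error(hla_mismatch_score(9), "0..8")
  scores <- vapply(0:8, hla_mismatch_score, integer(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("ABO compatibility reproduces the donation table", {
  can <- list(O = c("O", "A", "B", "AB"), A = c("A", "AB"),
              B = c("B", "AB"), AB = "AB")
  for (d in names(can)) {
    for (r in c("O", "A", "B", "AB")) {
      expect_identical(abo_compatible(d, r), r %in% can[[d]],
                       label = paste(d, "->", r))
    }
  }
  expect_true(abo_compatible("O", "AB"))
  expect_false(abo_compatible("A", "O"))
  expect_error(abo_compatible("X", "O"), "blood group")
})

test_that("ABO score penalises incompatibility without excluding", {
  expect_equal(abo_score("O", "A"), 1)
  expect_equal(abo_score("B", "A"), 0)
  cfg5 <- kex_weights(scores_abo = c(5L, 0L))
  expect_equal(abo_score("O", "O", cfg5), 5)
})

test_that("age, sex and weight scores follow the clinical orderings", {
  expect_equal(age_score(40, 40), 2)
  expect_equal(age_score(40, 70), 1)
  expect_equal(age_score(70, 40), 0)
  expect_equal(age_score(70, 70), 2) # senior-senior is intra-categorical
  expect_equal(age_score(55, 40), 0) # exactly 55 counts as senior

  expect_equal(sex_score("M", "M"), 2)
  expect_equal(sex_score("F", "F"), 2)
  expect_equal(sex_score("M", "F"), 1)
  expect_equal(sex_score("F", "M"), 0)

  expect_equal(weight_score(80, 70), 1)
  expect_equal(weight_score(60, 90), 0)
  expect_equal(weight_score(75, 75), 1)
  cfgm <- kex_weights(weight_margin_kg = 5)
  expect_equal(weight_score(71, 75, cfgm), 1)
})

test_that("edge weight gates on the crossmatch and is the weighted dot product", {
  d <- list(hla = list(A = "A23"), abo = "O", age = 40, sex = "M",
            weight_kg = 80)
  r_hit <- list(hla = list(A = "A25"), antibodies = "A23", abo = "O",
                age = 40, sex = "M", weight_kg = 70)
  expect_equal(edge_weight(d, r_hit), 0)

  r_ok <- list(hla = list(A = "A23"), antibodies = character(), abo = "A",
               age = 45, sex = "M", weight_kg = 70)
  # scores: hla 0 mismatches -> 3, abo 1, age 2, sex 2, weight 1; sum 9
  cs <- criterion_scores(d, r_ok)
  expect_true(cs$crossmatch)
  expect_equal(unname(cs$scores), c(3, 1, 2, 2, 1))
  expect_equal(edge_weight(d, r_ok), 1 + 9)
  cfg0 <- kex_weights(baseline = 0L)
  expect_equal(edge_weight(d, r_ok, cfg0), 9)
  # baseline-only: all criterion scores forced to zero
  cfgz <- kex_weights(bins_hla = c(0L, 0L, 0L, 0L),
                      scores_abo = c(0L, 0L), scores_age = c(0L, 0L, 0L),
                      scores_sex = c(0L, 0L, 0L),
                      scores_weight = c(0L, 0L), baseline = 1L)
  expect_equal(edge_weight(d, r_ok, cfgz), 1)
})

test_that("edge weight is monotone in weights and never negative", {
  d <- list(hla = list(A = "A23", B = "B38"), abo = "O", age = 40,
            sex = "F", weight_kg = 80)
  r <- list(hla = list(A = "A24"), antibodies = character(), abo = "B",
            age = 60, sex = "M", weight_kg = 90)
  base <- edge_weight(d, r)
  for (crit in c("hla_quality", "abo", "age", "sex", "weight")) {
    w <- c(hla_quality = 1L, abo = 1L, age = 1L, sex = 1L, weight = 1L)
    w[crit] <- 4L
    expect_gte(edge_weight(d, r, kex_weights(w = w)), base)
  }
  expect_gte(base, 0)
})
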