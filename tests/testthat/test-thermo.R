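test_that("identical sequences align with full identity and no gaps", {
  aln <- needleman_wunsch("ACDE", "ACDE")
  expect_equal(aln$identity_count, 4L)
  expect_equal(aln$alignment_length, 4L)
  expect_equal(aln$gap_count, 0L)
  expect_equal(nrow(aln$map), 4L)
})

simple_matrix <- function(match = 1, mismatch = -1) {
  ab <- c("A", "C", "D", "G", "T", "E")
  m <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- match
  m
}

test_that("a linear-gap toy alignment reproduces the known optimum", {
  sm <- simple_matrix()
  aln <- needleman_wunsch("ACD", "AD", substitution_matrix = sm,
                          gap_open = 0, gap_extend = 1)
  expect_equal(aln$score, 1)
  expect_equal(aln$alnA, "ACD")
  expect_equal(aln$alnB, "A-D")
})

test_that("alignment scores equal the exhaustive-search optimum", {
  sm <- simple_matrix(2, -1)
  set.seed(41)
  ab <- c("A", "C", "G", "T")
  for (rep_ in 1:50) {
    a <- paste(sample(ab, sample(1:7, 1), TRUE), collapse = "")
    b <- paste(sample(ab, sample(1:7, 1), TRUE), collapse = "")
    got <- needleman_wunsch(a, b, substitution_matrix = sm,
                            gap_open = 2, gap_extend = 0.5)$score
    want <- oracle_align_score(a, b, sm, open = 2, extend = 0.5)
    expect_equal(got, want, tolerance = 1e-9,
                 label = paste("score for", a, "vs", b))
  }
})

test_that("alignment score is symmetric under a symmetric matrix", {
  set.seed(55)
  ab <- c("A", "C", "G", "T")
  for (rep_ in 1:10) {
    a <- paste(sample(ab, 6, TRUE), collapse = "")
    b <- paste(sample(ab, 5, TRUE), collapse = "")
    s1 <- needleman_wunsch(a, b, simple_matrix(), 1, 0.5)$score
    s2 <- needleman_wunsch(b, a, simple_matrix(), 1, 0.5)$score
    expect_equal(s1, s2)
  }
})

test_that("alignment input validation", {
  expect_error(needleman_wunsch("", "ACD"), "empty sequence")
  expect_error(needleman_wunsch("AC1", "ACD"), "unknown letter")
})

scan_setup <- local({
  ctx <- NULL
  function() {
    if (is.null(ctx)) {
      sA <- annotate_structure(make_fixture_structure(
        "helix", 18, sequence = "random", seed = 21))
      sB <- annotate_structure(make_fixture_structure(
        "helix", 18, sequence = "random", seed = 22))
      structs <- fixture_pair()
      mt <- simulate_mutation_table(structs, 150, seed = 31)
      X <- encode_table(mt, structs)
      y <- simulate_ddg(X, recovery_coefficients(X), noise_sd = 0.3,
                        seed = 32)
      model <- train_model(X, y, seed = 33)
      ctx <<- list(sA = sA, sB = sB, model = model)
    }
    ctx
  }
})

test_that("identical structures yield an empty scan", {
  cc <- scan_setup()
  aln <- needleman_wunsch(structure_sequence(cc$sA),
                          structure_sequence(cc$sA))
  sc <- bidirectional_scan(cc$sA, cc$sA, aln, cc$model)
  expect_equal(sc$n_substituted, 0L)
  expect_equal(sc$totals$n_increase, c(0L, 0L))
  expect_equal(sc$totals$energy_sum, c(0, 0))
})

test_that("scan counts and energy sums are internally consistent", {
  cc <- scan_setup()
  aln <- needleman_wunsch(structure_sequence(cc$sA),
                          structure_sequence(cc$sB))
  sc <- bidirectional_scan(cc$sA, cc$sB, aln, cc$model,
                           envA = list(ph = 7, temp = 25),
                           envB = list(ph = 7, temp = 65))
  for (d in c("AtoB", "BtoA")) {
    tot <- sc$totals[sc$totals$direction == d, ]
    sites <- sc$sites[sc$sites$direction == d, ]
    expect_equal(tot$n_increase + tot$n_decrease, nrow(sites))
    expect_equal(tot$energy_sum, sum(sites$ddg), tolerance = 1e-9)
    expect_true(all(sites$exposure %in% c("buried", "exposed")))
  }
  # deterministic
  sc2 <- bidirectional_scan(cc$sA, cc$sB, aln, cc$model,
                            envA = list(ph = 7, temp = 25),
                            envB = list(ph = 7, temp = 65))
  expect_identical(sc$sites$ddg, sc2$sites$ddg)
})

test_that("the hypothesis report aggregates pairs and totals", {
  cc <- scan_setup()
  aln <- needleman_wunsch(structure_sequence(cc$sA),
                          structure_sequence(cc$sB))
  sc <- bidirectional_scan(cc$sA, cc$sB, aln, cc$model)
  rep_ <- hypothesis_report(list(p1 = sc, p2 = sc))
  expect_equal(nrow(rep_$pairs), 3L)
  tot <- rep_$pairs[rep_$pairs$pair == "Total", ]
  expect_equal(tot$TtoM_increase, 2 * sc$totals$n_increase[2])
  pct <- rep_$support$pct_decrease_all
  sites <- sc$sites[sc$sites$direction == "BtoA", ]
  expect_equal(pct, 100 * mean(sites$effect == "decrease"), tolerance = 1e-9)
})

test_that("an empty direction reports NA percentages, not zero", {
  cc <- scan_setup()
  aln <- needleman_wunsch(structure_sequence(cc$sA),
                          structure_sequence(cc$sA))
  sc <- bidirectional_scan(cc$sA, cc$sA, aln, cc$model)
  rep_ <- hypothesis_report(list(sc))
  expect_true(is.na(rep_$support$pct_decrease_all))
})
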