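test_that("stage 1 leaves CD/DC, DA/AD and tetramer D (plus coexisting monomers)", {
  res <- eliminate_false_positives(reported_feasibility_table(),
                                   trk1_terminal_observations())
  expect_setequal(res$candidates, c("dimer_CD", "dimer_DA", "tetramer_D"))
  expect_identical(res$coexisting, "monomer")
  expect_setequal(res$eliminated$arrangement,
                  c("dimer_AB", "dimer_BC", "tetramer_A", "tetramer_B", "tetramer_C"))
  expect_true(all(res$eliminated$experiment == "nn"))
})

test_that("an empty observation list eliminates nothing", {
  tab <- reported_feasibility_table()
  res <- eliminate_false_positives(tab, bifc_observations(character(0), character(0)))
  expect_setequal(c(res$candidates, res$coexisting),
                  unique(tab$entries$arrangement))
  expect_identical(nrow(res$eliminated), 0L)
})

test_that("a table feasible everywhere is fully eliminated by one negative", {
  arrs <- c("dimer_AB", "dimer_CD")
  entries <- expand.grid(arrangement = arrs, experiment = c("e1", "e2"),
                         stringsAsFactors = FALSE)
  entries$verdict <- "feasible"
  tab <- as_feasibility_table(entries)
  res <- eliminate_false_positives(tab, bifc_observations("e1", "no_bifc"))
  expect_length(res$candidates, 0L)
  expect_setequal(res$eliminated$arrangement, arrs)
})

test_that("blocked verdicts survive stage 1 but do not satisfy stage 2", {
  entries <- data.frame(
    arrangement = rep("dimer_DA", 2),
    experiment = c("neg", "pos"),
    verdict = c("blocked", "blocked"), stringsAsFactors = FALSE
  )
  tab <- as_feasibility_table(entries)
  s1 <- eliminate_false_positives(tab, bifc_observations("neg", "no_bifc"))
  expect_identical(s1$candidates, "dimer_DA")
  s2 <- require_explanation(s1$candidates, tab, bifc_observations("pos", "bifc_seen"))
  expect_length(s2$candidates, 0L)
})

test_that("the loop-3 positive leaves only the CD/DC dimer", {
  tab <- reported_feasibility_table()
  res <- require_explanation(c("dimer_CD", "dimer_DA", "tetramer_D"), tab,
                             trk1_discriminator_observations())
  expect_identical(res$candidates, "dimer_CD")
  # with no discriminators the candidates are unchanged
  res0 <- require_explanation(c("dimer_CD", "dimer_DA"), tab,
                              bifc_observations(character(0), character(0)))
  expect_setequal(res0$candidates, c("dimer_CD", "dimer_DA"))
  # a loop3-infeasible candidate is excluded
  res1 <- require_explanation("dimer_AB", tab, trk1_discriminator_observations())
  expect_length(res1$candidates, 0L)
})

test_that("full inference concludes the CD-interface dimer with named eliminations", {
  t0 <- Sys.time()
  res <- run_inference()
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_identical(res$candidates, "dimer_CD")
  expect_identical(res$coexisting, "monomer")
  expect_identical(nrow(res$eliminated), 7L)
  expect_identical(
    res$eliminated$experiment[res$eliminated$arrangement == "dimer_DA"], "loop3")
  expect_identical(
    res$eliminated$experiment[res$eliminated$arrangement == "tetramer_C"], "nn")
  expect_identical(nrow(res$rule_trace), 2L)
})

test_that("unknown experiment ids in observations are rejected", {
  tab <- reported_feasibility_table()
  expect_error(eliminate_false_positives(tab, bifc_observations("zz", "no_bifc")),
               "unknown experiment")
  expect_error(require_explanation("dimer_CD", tab,
                                   bifc_observations("zz", "bifc_seen")),
               "unknown experiment")
  expect_error(require_explanation("nonesuch", tab,
                                   trk1_discriminator_observations()),
               "not in table")
})

test_that("staged engine equals the definitional set-filter on random inputs", {
  set.seed(42)
  exps <- c("nn", "vcn_vnc", "vnn_vcc", "cc", "loop3")
  for (rep in 1:60) {
    tab <- random_table()
    term <- random_observations(exps)
    disc <- random_observations(exps)
    oracle <- inference_oracle(tab, term, disc)
    s1 <- eliminate_false_positives(tab, term)
    expect_setequal(s1$candidates, oracle$stage1)
    res <- run_inference(tab, term, disc)
    expect_setequal(res$candidates, oracle$final)
    expect_identical(length(res$coexisting) > 0, oracle$monomer)
    # partition invariant: candidates, coexisting and eliminated partition
    # the arrangements
    all_ids <- unique(tab$entries$arrangement)
    expect_setequal(c(res$candidates, res$coexisting, res$eliminated$arrangement),
                    all_ids)
    expect_identical(anyDuplicated(c(res$candidates, res$coexisting,
                                     res$eliminated$arrangement)), 0L)
  }
})

test_that("candidates never grow as evidence accumulates and observation order is irrelevant", {
  set.seed(7)
  exps <- c("nn", "vcn_vnc", "vnn_vcc", "cc", "loop3")
  for (rep in 1:20) {
    tab <- random_table()
    obs <- random_observations(exps, n = 4L)
    prev <- Inf
    for (k in 0:nrow(obs)) {
      res <- run_inference(tab, head(obs, k), trk1_discriminator_observations())
      n_cand <- length(res$candidates)
      expect_lte(n_cand, prev)
      prev <- n_cand
    }
    shuffled <- obs[sample(nrow(obs)), , drop = FALSE]
    r1 <- run_inference(tab, obs, trk1_discriminator_observations())
    r2 <- run_inference(tab, shuffled, trk1_discriminator_observations())
    expect_setequal(r1$candidates, r2$candidates)
  }
})

test_that("consistency results export to JSON", {
  path <- tempfile(fileext = ".json")
  write_consistency_result(run_inference(), path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(parsed$candidates, "dimer_CD")
  expect_identical(parsed$coexisting, "monomer")
})
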