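test_that("note selection by PHI count hits the budget with whole notes", {
  corp <- tiny_corpus(40, seed = 17)
  expect_equal(length(select_notes_by_phi_count(corp, "NAME", 0)), 0L)
  counts <- vapply(corp$notes, function(n) sum(n$spans$type == "NAME"),
                   integer(1))
  n_target <- 15L
  sub <- select_notes_by_phi_count(corp, "NAME", n_target, seed = 2)
  got <- sum(vapply(sub$notes, function(n) sum(n$spans$type == "NAME"),
                    integer(1)))
  expect_gte(got, n_target)
  # overshoot is less than the last selected note's own count
  expect_lt(got - max(vapply(sub$notes, function(n)
    sum(n$spans$type == "NAME"), integer(1))), n_target)
  expect_identical(select_notes_by_phi_count(corp, "NAME", n_target, seed = 2),
                   sub)
  expect_error(select_notes_by_phi_count(corp, "NAME", sum(counts) + 1L),
               "instances")
  # one instance per note forces exactly n notes
  notes <- lapply(1:25, function(i)
    annotated_note(paste0("n", i), "Patient John Smith was admitted.",
                   phi_span(8, 18, "NAME"), patient_id = paste0("p", i)))
  one_each <- deid_corpus(notes)
  expect_equal(length(select_notes_by_phi_count(one_each, "NAME", 20L,
                                                seed = 1)), 20L)
})

test_that("scenario preconditions are enforced", {
  corp <- tiny_corpus(10, seed = 18)
  expect_error(scenario_config("off_the_shelf", corpus_a = corp),
               "requires corpus_b")
  expect_error(scenario_config("only_b", corpus_b = corp, n_labeled = 0),
               "n_labeled")
  expect_error(scenario_config("a_mix_b", corpus_a = corp, corpus_b = corp,
                               n_labeled = 0), "n_labeled")
})

test_that("scenario runs keep train and test patients disjoint and are
           reproducible, with a_then_b(n=0) reducing to off_the_shelf", {
  pair <- generate_domain_pair(
    gen_preset("i2b2-2014", n_notes = 40, seed = 19),
    gen_preset("nursing", n_notes = 30, seed = 20,
               jargon_set = c("MICU", "SDU")),
    shared_fraction = 0.6)
  mcfg <- small_mcfg()
  tcfg <- small_tcfg(max_epochs = 3)
  ots <- run_scenario(scenario_config("off_the_shelf", pair$a, pair$b,
                                      seed = 1), mcfg, tcfg)
  # test notes come from B's held-out patients only
  test_pats <- unique(deidtag:::corpus_patients(ots$test))
  train_pats <- unique(deidtag:::corpus_patients(
    split_by_patient(pair$b, 0.75, seed = 1)$train))
  expect_length(intersect(test_pats, train_pats), 0)
  # a_then_b with n = 0 is the off-the-shelf model
  atb0 <- run_scenario(scenario_config("a_then_b", pair$a, pair$b,
                                       n_labeled = 0, seed = 1), mcfg, tcfg)
  expect_identical(atb0$model$params, ots$model$params)
  expect_equal(atb0$report$token, ots$report$token)
  # identical config and seed reproduce the result exactly
  ots2 <- run_scenario(scenario_config("off_the_shelf", pair$a, pair$b,
                                       seed = 1), mcfg, tcfg)
  expect_identical(ots2$report, ots$report)
  expect_identical(ots2$rp$sweep, ots$rp$sweep)
})

test_that("a_mix_b trains on evenly mixed batches and evaluates on B", {
  pair <- generate_domain_pair(
    gen_preset("i2b2-2014", n_notes = 30, seed = 25),
    gen_preset("nursing", n_notes = 24, seed = 26,
               jargon_set = c("MICU", "SDU")),
    shared_fraction = 0.6)
  res <- run_scenario(scenario_config("a_mix_b", pair$a, pair$b,
                                      n_labeled = 6, seed = 1),
                      small_mcfg(), small_tcfg(max_epochs = 2))
  expect_s3_class(res$report, "eval_report")
  expect_equal(res$mode, "a_mix_b")
  # the test partition is B's held-out split
  expect_true(all(grepl("nursing", deidtag:::corpus_patients(res$test))))
  expect_true(is.finite(res$rp$recall))
})

test_that("learning curves emit one row per strategy, budget and replicate", {
  pair <- generate_domain_pair(
    gen_preset("i2b2-2014", n_notes = 30, seed = 21),
    gen_preset("nursing", n_notes = 24, seed = 22,
               jargon_set = c("MICU", "SDU")),
    shared_fraction = 0.6)
  curve <- learning_curve(pair$a, pair$b, ns = c(0L, 8L),
                          strategies = c("only_b", "a_then_b"),
                          replicates = 2L, mcfg = small_mcfg(),
                          tcfg = small_tcfg(max_epochs = 2), seed = 1)
  expect_equal(nrow(curve), 2L * 2L * 2L)
  expect_equal(sort(unique(curve$strategy)), c("a_then_b", "only_b"))
  # only_b has no n = 0 point by construction
  expect_true(all(is.na(curve$recall[curve$strategy == "only_b" &
                                     curve$n == 0])))
  expect_true(all(!is.na(curve$recall[curve$strategy == "a_then_b"])))
})
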