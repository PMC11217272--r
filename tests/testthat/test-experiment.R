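test_that("the pair inventory has the published structure", {
  pairs <- phoneme_pairs()
  expect_identical(nrow(pairs), 45L)
  expect_identical(sum(pairs$phoneme_type == "consonant"), 27L)
  expect_identical(sum(pairs$phoneme_type == "vowel"), 18L)
  tab <- table(pairs$contrast_type)
  expect_identical(unname(tab["monophthong"]), 12L)
  expect_identical(unname(tab["diphthong"]), 6L)
  cons_groups <- setdiff(names(tab), c("monophthong", "diphthong"))
  expect_identical(length(cons_groups), 9L)
  expect_true(all(tab[cons_groups] == 3L))
  # the voicing subgroup is exactly {z&s, ezh&esh, theta&eth}
  v <- pairs[pairs$contrast_type == "voicing", ]
  expect_identical(nrow(v), 3L)
  expected <- list(c("z", "s"), c("\u0292", "\u0283"),
                   c("\u03b8", "\u00f0"))
  for (pr in expected) {
    hit <- (v$phoneme_a == pr[1] & v$phoneme_b == pr[2]) |
      (v$phoneme_a == pr[2] & v$phoneme_b == pr[1])
    expect_true(any(hit), info = paste(pr, collapse = "&"))
  }
  # every phoneme used is in the inventory
  inv <- phoneme_inventory()
  expect_true(all(c(pairs$phoneme_a, pairs$phoneme_b) %in% inv$label))
})

test_that("the trial schedule reproduces the published counts for any seed", {
  for (seed in c(1, 999)) {
    tr <- generate_trial_list(seed = seed)
    expect_identical(nrow(tr), 720L)
    expect_true(all(table(tr$condition) == 180L))
    expect_true(all(table(tr$condition, tr$phoneme_type)[, "consonant"] == 108L))
    expect_true(all(table(tr$condition, tr$phoneme_type)[, "vowel"] == 72L))
    # every pair occurs equally often in every condition
    expect_true(all(table(tr$condition, tr$pair_id) == 4L))  # 2 talkers x 2 reps
    # subgroup counts per condition
    sub <- table(tr$condition, tr$contrast_type)
    expect_true(all(sub[, "monophthong"] == 48L))
    expect_true(all(sub[, "diphthong"] == 24L))
    cons <- setdiff(colnames(sub), c("monophthong", "diphthong"))
    expect_true(all(sub[, cons] == 12L))
    # within-repeat balance
    expect_true(all(table(tr$repeat_block) == 360L))
  }
})

test_that("per-trial draws are valid and the odd interval is uniform", {
  tr <- generate_trial_list(seed = 8)
  expect_true(all(tr$odd_interval %in% 1:3))
  expect_true(all(tr$token_odd %in% 1:4 & tr$token_std %in% 1:4))
  expect_true(all(abs(tr$rove_db_1) <= 3 & abs(tr$rove_db_2) <= 3 &
                    abs(tr$rove_db_3) <= 3))
  expect_true(all(tr$odd_phoneme != tr$std_phoneme))
  # aggregate many schedules: odd position approaches uniformity
  set.seed(10)
  pos <- unlist(lapply(1:40, function(i) generate_trial_list()$odd_interval))
  freq <- table(pos) / length(pos)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("scoring is exact for perfect and near-chance for random responders", {
  tr <- generate_trial_list(seed = 4)
  sc <- score_responses(tr, tr$odd_interval)
  expect_true(all(sc$by_type$percent_correct == 100))
  expect_true(all(sc$by_contrast$percent_correct == 100))
  expect_identical(sum(sc$by_type$n), 720L)
  # random responder over many schedules sits at chance (1/3)
  set.seed(20)
  hits <- unlist(lapply(1:50, function(i) {
    t2 <- generate_trial_list()
    sample.int(3, nrow(t2), replace = TRUE) == t2$odd_interval
  }))
  expect_equal(mean(hits), 1 / 3, tolerance = 0.01)
})

test_that("scoring rejects missing responses and ignores trial order", {
  tr <- generate_trial_list(seed = 12)
  resp <- tr$odd_interval
  bad <- resp
  bad[c(5, 9)] <- NA
  expect_error(score_responses(tr, bad), "5, 9")
  # permutation invariance
  perm <- sample.int(nrow(tr))
  sc1 <- score_responses(tr, resp)
  sc2 <- score_responses(tr[perm, ],
                         data.frame(trial = tr$trial, response = resp))
  expect_equal(sc1$by_type[order(sc1$by_type$condition, sc1$by_type$talker,
                                 sc1$by_type$phoneme_type), ],
               sc2$by_type[order(sc2$by_type$condition, sc2$by_type$talker,
                                 sc2$by_type$phoneme_type), ],
               ignore_attr = TRUE)
})
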