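test_that("bigram counting reproduces worked examples", {
  c1 <- count_bigrams(state_sequence("SSSLS"))
  expect_equal(c1[["SS"]], 2)
  expect_equal(c1[["SL"]], 1)
  expect_equal(c1[["LS"]], 1)
  expect_equal(sum(c1), 4)

  c2 <- count_bigrams(state_sequence("SSLSS"))
  expect_equal(c2[["SS"]], 2)
  expect_equal(c2[["SL"]], 1)
  expect_equal(c2[["LS"]], 1)

  # every adjacent pair enumerated by hand
  c3 <- count_bigrams(state_sequence("SLMVS"))
  expect_equal(c3[["SL"]], 1)
  expect_equal(c3[["LM"]], 1)
  expect_equal(c3[["MV"]], 1)
  expect_equal(c3[["VS"]], 1)
  expect_equal(sum(c3), 4)

  # single-epoch sequence has no pairs
  expect_equal(sum(count_bigrams(state_sequence("S"))), 0)
})

test_that("pairs touching missing epochs contribute to no bigram", {
  c1 <- count_bigrams(state_sequence("SS.LL"))
  expect_equal(c1[["SS"]], 1)
  expect_equal(c1[["LL"]], 1)
  expect_equal(c1[["SL"]], 0)
  expect_equal(attr(c1, "n_valid_pairs"), 2)
})

test_that("bigram profiles divide raw counts by D", {
  expect_equal(bigram_profile(state_sequence("SSSLS"), D = 1)$b[["SS"]], 2)
  expect_equal(bigram_profile(state_sequence("SSSLS"), D = 7)$b[["SS"]], 2 / 7)
  expect_error(bigram_profile(state_sequence("SSSLS"), D = 0),
               class = "actibigram_invalid_parameter")
  expect_error(state_durations(state_sequence("SSSLS"), D = -1),
               class = "actibigram_invalid_parameter")
})

test_that("bigram counts match a brute-force pair enumeration on random masked sequences", {
  set.seed(2024)
  for (rep in 1:25) {
    seq <- random_state_sequence(sample(2:400, 1), p_missing = 0.3)
    counts <- count_bigrams(seq)
    oracle <- brute_force_bigram_counts(seq$states)
    for (a in activity_states()) {
      for (b in activity_states()) {
        expect_equal(counts[[paste0(a, b)]], oracle[a, b])
      }
    }
    expect_equal(sum(counts), sum(oracle))
  }
})

test_that("u-bigram profiles collapse reciprocal bigrams and keep diagonals", {
  # SLS: one SL pair and one LS pair -> [SL] = 2
  p <- bigram_profile(state_sequence("SLS"), D = 1)
  up <- ubigram_profile(p)
  expect_equal(up$bu[["[SL]"]], 2)
  # SSS: [SS] equals the SS bigram, not doubled
  p2 <- bigram_profile(state_sequence("SSS"), D = 1)
  expect_equal(ubigram_profile(p2)$bu[["[SS]"]], 2)
  # all-missing profile collapses to zeros
  p3 <- bigram_profile(state_sequence(c(NA, NA, NA)), D = 1)
  expect_true(all(ubigram_profile(p3)$bu == 0))
})

test_that("u-bigram consistency and reversal symmetry hold on random sequences", {
  set.seed(99)
  st <- activity_states()
  for (rep in 1:20) {
    seq <- random_state_sequence(sample(5:300, 1), p_missing = 0.25)
    p <- bigram_profile(seq, D = 3)
    up <- ubigram_profile(p)
    for (i in seq_along(st)) {
      for (j in i:length(st)) {
        key <- paste0("[", st[i], st[j], "]")
        expected <- if (i == j) p$b[[paste0(st[i], st[i])]] else
          p$b[[paste0(st[i], st[j])]] + p$b[[paste0(st[j], st[i])]]
        expect_equal(up$bu[[key]], expected)
      }
    }
    # reversing the sequence swaps b(A,B) and b(B,A), leaves bu unchanged
    rev_seq <- state_sequence(rev(seq$states), n_days = seq$n_days,
                              epochs_per_day = seq$epochs_per_day)
    p_rev <- bigram_profile(rev_seq, D = 3)
    for (a in st) {
      for (b in st) {
        expect_equal(p_rev$b[[paste0(a, b)]], p$b[[paste0(b, a)]])
      }
    }
    expect_equal(ubigram_profile(p_rev)$bu, up$bu)
  }
})

test_that("state durations count worn minutes per state per day", {
  d <- state_durations(state_sequence("SSSLS"), D = 1)
  expect_equal(c(d$Sd, d$Ld, d$Md, d$Vd), c(4, 1, 0, 0))

  d2 <- state_durations(state_sequence(rep(NA_character_, 10)), D = 1)
  expect_equal(c(d2$Sd, d2$Ld, d2$Md, d2$Vd), rep(0, 4))

  set.seed(5)
  seq <- random_state_sequence(500, p_missing = 0.2)
  d3 <- state_durations(seq, D = 2)
  tallies <- table(factor(seq$states, levels = activity_states()))
  expect_equal(d3$Sd, unname(tallies[["S"]]) / 2)
  expect_equal(d3$Vd, unname(tallies[["V"]]) / 2)
  # conservation: total duration x D equals worn epochs
  expect_equal((d3$Sd + d3$Ld + d3$Md + d3$Vd) * 2, sum(!is.na(seq$states)))
})

test_that("bigram minute spans account for overlapping occurrences", {
  expect_equal(bigram_minute_span(state_sequence("SSSLS"), "SS"), 3)
  expect_equal(bigram_minute_span(state_sequence("SSLSS"), "SS"), 4)
  expect_equal(bigram_minute_span(state_sequence("SSLSS"), "MV"), 0)
  expect_equal(bigram_minute_span(state_sequence("S"), "SS"), 0)
  expect_error(bigram_minute_span(state_sequence("SS"), "SX"),
               class = "actibigram_invalid_input")
})

test_that("pairs spanning day boundaries inside the recording are included", {
  # 2 days of 3 epochs: ...S | L... junction pair SL must be counted
  seq <- state_sequence(c("S", "S", "S", "L", "L", "L"), n_days = 2,
                        epochs_per_day = 3)
  counts <- count_bigrams(seq)
  expect_equal(counts[["SL"]], 1)
  expect_equal(attr(counts, "n_valid_pairs"), 5)
})

test_that("feature rows carry profiles, durations and summaries consistently", {
  set.seed(11)
  counts <- sample(0:6500, 3 * 1440, replace = TRUE)
  es <- detect_nonwear(epoch_series("p7", counts, n_days = 3))
  row <- compute_features(es)
  expect_equal(row$participant_id, "p7")
  expect_equal(row$D, 3)
  # conservation against the profile invariant
  bigram_sum <- sum(unlist(row[bigram_names()]))
  expect_equal(bigram_sum * 3, row$n_valid_pairs)
  expect_equal(row$u_SL, row$SL + row$LS)
  expect_equal(row$u_MM, row$MM)
  ws <- wear_summaries(es)
  expect_equal(row$mCPM, ws$mCPM)
  expect_equal(row$sdCPM, ws$sdCPM)
})

test_that("the valid-days-only policy drops invalid days and pairs spanning them", {
  rules <- validity_rules(valid_day_min_wear_epochs = 3, min_valid_days = 1)
  # day 1 fully worn (SSSS); day 2 has only 2 worn epochs -> invalid
  mask <- c(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE))
  es <- epoch_series("p", rep(50L, 8), n_days = 2, epochs_per_day = 4,
                     missing_mask = mask)
  row_all <- compute_features(es, rules = rules, day_policy = "all_days")
  expect_equal(row_all$D, 2)
  expect_equal(row_all$SS, (3 + 1) / 2)  # 3 pairs in day 1, 1 pair in day 2

  row_valid <- compute_features(es, rules = rules,
                                day_policy = "valid_days_only")
  expect_equal(row_valid$D, 1)
  expect_equal(row_valid$SS, 3)  # day 2 removed; junction pair dropped
  expect_equal(row_valid$n_valid_pairs, 3)

  # no valid days at all -> dedicated error
  rules_strict <- validity_rules(valid_day_min_wear_epochs = 5,
                                 min_valid_days = 1)
  expect_error(compute_features(es, rules = rules_strict,
                                day_policy = "valid_days_only"),
               class = "actibigram_no_valid_days")
})

test_that("build_feature_table screens invalid participants and reports reasons", {
  ok <- epoch_series("ok", rep(300L, 7 * 1440))
  hot <- epoch_series("hot", rep(1600L, 7 * 1440))  # mCPM too high
  ft <- build_feature_table(list(ok, hot))
  expect_equal(nrow(ft$validity), 2)
  expect_equal(ft$features$participant_id, "ok")
  expect_false(ft$validity$valid[ft$validity$participant_id == "hot"])
  expect_match(ft$validity$reasons[ft$validity$participant_id == "hot"],
               "mean cpm")
  # keep_invalid retains the flagged participant's features
  ft2 <- build_feature_table(list(ok, hot), keep_invalid = TRUE)
  expect_equal(nrow(ft2$features), 2)
})
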