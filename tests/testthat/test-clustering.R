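# The default synthetic fixture is reused across several tests.
fixture <- generate_synthetic_engagers(seed = 42)
fixture_clusters <- cluster_engagers(fixture)

test_that("percent contrasts reproduce the published feature reductions", {
  prof <- role_feature_means()
  adv <- prof[prof$role == "advocate", ]
  sup <- prof[prof$role == "supporter", ]
  expect_equal(percent_reduction(adv$n_mentions, sup$n_mentions), 36.7)
  expect_equal(percent_reduction(adv$n_topics, sup$n_topics), 52.8)
  expect_equal(percent_reduction(adv$n_links, sup$n_links), 53.9)
  # the original-message contrast computes to 95.0 under round-half-up
  expect_equal(percent_reduction(adv$n_original, sup$n_original), 95.0)
  expect_equal(percent_reduction(0.7, 0.7), 0)
  expect_error(percent_reduction(0, 0.1), "positive",
               class = "i2s2r_validation_error")
})

test_that("the published role profile and observation window are consistent", {
  prof <- role_feature_means()
  expect_equal(sum(prof$n_people), 194183L)
  expect_equal(observation_window_days(), 45L)
  expect_equal(observation_window_days("2020-03-01", "2020-03-01"), 1L)
  expect_error(observation_window_days("2020-03-02", "2020-03-01"),
               class = "i2s2r_validation_error")
})

test_that("the generator matches its target means and structural zeros", {
  tab <- generate_synthetic_engagers(100, 100, 100, seed = 3)
  expect_equal(nrow(tab), 300L)
  expect_false(anyDuplicated(tab$user_id) > 0)
  amp <- tab[tab$group == "amplifier", ]
  expect_true(all(amp[, c("n_original", "n_mentions", "n_topics", "n_links")] == 0))
  expect_true(all(amp$n_shares > 0))
  expect_equal(nrow(generate_synthetic_engagers(0, 0, 0, seed = 1)), 0L)
  # determinism
  expect_equal(generate_synthetic_engagers(50, 50, 50, seed = 9),
               generate_synthetic_engagers(50, 50, 50, seed = 9))
  # law of large numbers against the generator's own target means
  big <- generate_synthetic_engagers(3000, 3000, 0, seed = 4)
  adv <- big[big$group == "advocate", ]
  expect_lt(abs(mean(adv$n_original) - 34.571) / 34.571, 0.1)
  sup <- big[big$group == "supporter", ]
  # supporter rare-feature means are exact up to the rounding of the total
  expect_equal(mean(sup$n_mentions), 0.193, tolerance = 1e-3)
  expect_equal(mean(sup$n_topics), 0.482, tolerance = 1e-3)
})

test_that("DBSCAN handles degenerate inputs and is order-invariant", {
  one <- data.frame(user_id = "u1", n_original = 5, n_mentions = 0,
                    n_topics = 1, n_links = 0, n_shares = 2)
  s1 <- cluster_engagers(one, eps = 0.5, min_pts = 1)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$size, 1L)
  expect_equal(s1$label, "advocate")
  expect_error(cluster_engagers(one[0, ]), "empty",
               class = "i2s2r_validation_error")
  # widely spread points with a demanding core threshold: everything is noise
  spread <- data.frame(user_id = paste0("u", 1:8),
                       n_original = c(0, 50, 100, 150, 200, 250, 300, 350),
                       n_mentions = 0, n_topics = 0, n_links = 0,
                       n_shares = seq(0, 700, by = 100))
  expect_warning(sn <- cluster_engagers(spread, eps = 0.1, min_pts = 5),
                 "noise")
  expect_equal(sn$label, "noise")
  expect_equal(sum(sn$size), 8L)
  # permuting the rows leaves the summary unchanged
  set.seed(5)
  perm <- fixture[sample.int(nrow(fixture)), ]
  sp <- cluster_engagers(perm)
  cols <- c("label", "cluster", "size", "n_original", "n_mentions",
            "n_topics", "n_links", "n_shares")
  expect_equal(as.data.frame(sp)[cols], as.data.frame(fixture_clusters)[cols])
  # per-user role assignments also survive the permutation
  la <- attr(sp, "labels"); lb <- attr(fixture_clusters, "labels")
  expect_equal(la[order(names(la))], lb[order(names(lb))])
})

test_that("the synthetic fixture separates into the three engager roles", {
  s <- fixture_clusters
  expect_equal(sum(s$size), nrow(fixture))        # conservation incl. noise
  clusters <- s[s$label != "noise", ]
  expect_equal(nrow(clusters), 3L)
  expect_setequal(clusters$label, c("advocate", "supporter", "amplifier"))
  expect_equal(clusters$n_original[clusters$label == "amplifier"], 0)
  expect_gt(clusters$n_original[clusters$label == "advocate"],
            clusters$n_original[clusters$label == "supporter"])
  # per-user labels agree with the generating groups away from noise
  lab <- attr(s, "labels")
  nn <- lab != "noise"
  expect_gte(mean(lab[nn] == fixture$group[nn]), 0.95)
})
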