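test_that("pair scores match hand values and are symmetric", {
  expect_equal(pair_agreement_single("teamleader", "teamleader"), 1)
  expect_equal(pair_agreement_single("teamleader", "anesthetist"), 0)
  # exhaustive symmetry over a 5-option item
  opts <- sprintf("o%d", 1:5)
  for (a in opts) for (b in opts) {
    expect_identical(pair_agreement_single(a, b), pair_agreement_single(b, a))
  }

  expect_equal(pair_overlap_multi(c("A", "B"), c("B", "C")), 1 / 3)
  for (m in c("jaccard", "dice", "overlap")) {
    expect_equal(pair_overlap_multi(c("A", "B"), c("A", "B"), m), 1)
    expect_equal(pair_overlap_multi("A", "B", m), 0)
  }
  expect_equal(pair_overlap_multi(c("A", "B"), c("B", "C"), "dice"), 0.5)
  expect_equal(pair_overlap_multi(c("A", "B"), c("B", "C"), "overlap"), 0.5)
  expect_error(pair_overlap_multi(character(0), "A"), "empty")
})

test_that("item similarity averages pair scores over all pairs", {
  expect_equal(item_similarity(list("X", "X", "Y"), "single"), 1 / 3)
  expect_equal(item_similarity(rep(list("X"), 5), "single"), 1)
  expect_equal(item_similarity(as.list(sprintf("o%d", 1:4)), "single"), 0)
  expect_true(is.na(item_similarity(list("X"), "single")))
  # empty selections are dropped, not scored 0
  expect_equal(item_similarity(list(c("A"), character(0), c("A")), "multi"), 1)
})

test_that("similarity engine matches brute-force pair enumeration", {
  set.seed(42)
  for (rep in 1:60) {
    k <- sample(2:9, 1); m <- sample(2:8, 1)
    mode <- sample(c("single", "multi"), 1)
    metric <- sample(c("jaccard", "dice", "overlap"), 1)
    sels <- random_selections(k, m, mode, allow_missing = TRUE)
    expect_equal(item_similarity(sels, mode, metric),
                 oracle_item_score(sels, mode, metric))
  }
})

test_that("study scoring equals an item-by-item oracle on random studies", {
  for (s in 1:4) {
    rs <- random_study(n_teams = 4, n_items = 6, m = 5, seed = 500 + s)
    st <- smm_study(rs$responses, rs$q)
    for (metric in c("jaccard", "dice", "overlap")) {
      sc <- score_study(st, metric = metric)
      items <- attr(sc, "item_scores")
      r <- st$responses
      for (i in sample(nrow(items), 20)) {
        row <- items[i, ]
        sel <- r[r$team_id == row$team_id & r$time == row$time &
                   r$item_id == row$item_id, ]
        sels <- unname(split(sel$option, sel$member_id))
        mode <- rs$q$items$response_mode[rs$q$items$item_id == row$item_id]
        expected <- oracle_item_score(sels, mode, metric)
        if (is.na(expected)) expect_true(is.na(row$score))
        else expect_equal(row$score, expected)
      }
      # aggregation identities
      for (j in sample(nrow(sc), 4)) {
        cell <- items[items$team_id == sc$team_id[j] & items$time == sc$time[j], ]
        def <- !is.na(cell$score)
        expect_equal(sc$total[j], mean(cell$score[def]))
        doms <- tapply(cell$score[def], cell$domain[def], mean)
        w <- table(cell$domain[def])
        expect_equal(sc$total[j],
                     sum(doms * as.numeric(w[names(doms)])) / sum(w))
      }
    }
  }
})

test_that("scores are invariant to member, team and row permutations", {
  rs <- random_study(n_teams = 4, n_items = 5, m = 4, seed = 901)
  st <- smm_study(rs$responses, rs$q)
  sc <- score_study(st)

  shuffled <- rs$responses[sample(nrow(rs$responses)), ]
  expect_equal(score_study(smm_study(shuffled, rs$q)), sc)

  relabel <- rs$responses
  relabel$member_id <- paste0("zz", relabel$member_id)
  sc2 <- score_study(smm_study(relabel, rs$q))
  expect_equal(sc2[setdiff(names(sc2), "n_members")],
               sc[setdiff(names(sc), "n_members")])
  expect_equal(sc2$n_members, sc$n_members)

  # duplicating a team under a new id reproduces its scores exactly
  dup <- rs$responses[rs$responses$team_id == "T1", ]
  dup$team_id <- "T9"
  sc3 <- score_study(smm_study(rbind(rs$responses, dup), rs$q))
  a <- sc3[sc3$team_id == "T1", setdiff(names(sc3), c("team_id"))]
  b <- sc3[sc3$team_id == "T9", setdiff(names(sc3), c("team_id"))]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("duplicating a modal responder never lowers a single-choice score", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(2:6, 1); m <- sample(2:5, 1)
    sels <- random_selections(k, m, "single")
    tabs <- table(unlist(sels))
    modal <- names(tabs)[which.max(tabs)]
    s0 <- item_similarity(sels, "single")
    s1 <- item_similarity(c(sels, modal), "single")
    expect_gte(s1, s0)
  }
})

test_that("degenerate and boundary studies score as expected", {
  # all members identical on every item -> all scores 1
  q <- questionnaire_spec(c("a", "b"), c("task_responsibility", "communication"),
                          c("single", "multi"),
                          list(c("x", "y"), c("p", "q", "r")))
  resp <- rbind(
    expand.grid(group = "g", team_id = "T1", member_id = c("A", "B", "C"),
                time = c("pre", "post"), item_id = "a", option = "x",
                stringsAsFactors = FALSE),
    expand.grid(group = "g", team_id = "T1", member_id = c("A", "B", "C"),
                time = c("pre", "post"), item_id = "b", option = c("p", "q"),
                stringsAsFactors = FALSE)
  )
  sc <- score_study(smm_study(resp, q))
  expect_true(all(sc$task_responsibility == 1, sc$communication == 1, sc$total == 1))

  # team of 3, two single items scoring 1/3 and 1 -> domain mean 2/3
  q2 <- questionnaire_spec(c("i1", "i2"), "task_responsibility", "single",
                           rep(list(c("x", "y", "z")), 2))
  r2 <- rbind(
    data.frame(group = "g", team_id = "T1", member_id = c("A", "B", "C"),
               time = "pre", item_id = "i1", option = c("x", "x", "y")),
    data.frame(group = "g", team_id = "T1", member_id = c("A", "B", "C"),
               time = "pre", item_id = "i2", option = "z")
  )
  st2 <- smm_study(r2, q2, time_points = "pre")
  tm <- score_team(st2, "T1", "pre")
  expect_equal(unname(tm$item_scores[c("i1", "i2")]), c(1 / 3, 1))
  expect_equal(unname(tm$domain_scores["task_responsibility"]), 2 / 3)
  expect_equal(tm$total, 2 / 3)
})

test_that("a 29-team study yields 58 score rows and a percent report", {
  st <- simulate_study(simulation_config(seed = 3))
  sc <- score_study(st)
  expect_equal(nrow(sc), 58L)
  expect_true(all(sc$n_items_scored == 54L))
  pct <- scores_as_percent(sc)
  expect_equal(pct$total, round(100 * sc$total, 2))
})
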