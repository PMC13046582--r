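# Independent brute-force oracles and random-instance builders used across
# the suite. These deliberately share no code with the package internals:
# plain set operations, explicit pair enumeration via combn(), and textbook
# formulas.

oracle_pair_score <- function(a, b, mode, metric = "jaccard") {
  a <- unique(a); b <- unique(b)
  if (mode == "single") return(as.numeric(identical(a, b)))
  i <- length(intersect(a, b))
  switch(metric,
    jaccard = i / length(union(a, b)),
    dice = 2 * i / (length(a) + length(b)),
    overlap = i / min(length(a), length(b))
  )
}

oracle_item_score <- function(sels, mode, metric = "jaccard") {
  sels <- sels[lengths(sels) > 0]
  k <- length(sels)
  if (k < 2) return(NA_real_)
  prs <- utils::combn(k, 2)
  mean(apply(prs, 2, function(ij) {
    oracle_pair_score(sels[[ij[1]]], sels[[ij[2]]], mode, metric)
  }))
}

# random member selections for one item
random_selections <- function(k, m, mode, allow_missing = FALSE) {
  opts <- sprintf("o%d", seq_len(m))
  lapply(seq_len(k), function(i) {
    if (allow_missing && runif(1) < 0.15) return(character(0))
    if (mode == "single") sample(opts, 1) else sample(opts, sample.int(m, 1))
  })
}

# small random study as a raw response data frame + its questionnaire
random_study <- function(n_teams = 4, n_items = 6, m = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  modes <- sample(c("single", "multi"), n_items, replace = TRUE)
  doms <- sample(c("task_responsibility", "communication"), n_items, replace = TRUE)
  q <- questionnaire_spec(
    item_id = sprintf("q%02d", seq_len(n_items)),
    domain = doms, response_mode = modes,
    options = lapply(seq_len(n_items), function(i) sprintf("o%d", seq_len(m)))
  )
  rows <- list()
  for (tt in seq_len(n_teams)) {
    k <- sample(3:6, 1)
    for (tp in c("pre", "post")) {
      for (it in seq_len(n_items)) {
        sels <- random_selections(k, m, modes[it], allow_missing = TRUE)
        for (mem in seq_len(k)) {
          sel <- sels[[mem]]
          if (!length(sel)) next
          rows[[length(rows) + 1]] <- data.frame(
            group = if (tt <= n_teams / 2) "A" else "B",
            team_id = sprintf("T%d", tt), member_id = sprintf("M%d", mem),
            time = tp, item_id = sprintf("q%02d", it), option = sel,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(q = q, responses = do.call(rbind, rows))
}

# textbook Pearson chi-square, no correction
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}

# pooled two-sample t^2 on change scores: the closed-form interaction oracle
oracle_interaction_f <- function(pre1, post1, pre2, post2) {
  d1 <- post1 - pre1; d2 <- post2 - pre2
  n1 <- length(d1); n2 <- length(d2)
  sp2 <- ((n1 - 1) * var(d1) + (n2 - 1) * var(d2)) / (n1 + n2 - 2)
  tt <- (mean(d1) - mean(d2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tt^2
}
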