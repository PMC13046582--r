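#' Pairwise agreement for single-choice selections
#'
#' Two members agree on a single-choice item when they selected the same
#' option; agreement is coded 1, disagreement 0. The coding is nominal and
#' symmetric.
#'
#' @param a,b Single selected options (length-1 character).
#' @return 0 or 1.
#' @examples
#' pair_agreement_single("teamleader", "teamleader")  # 1
#' pair_agreement_single("teamleader", "anesthetist") # 0
#' @export
pair_agreement_single <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L) {
    stop("single-choice selections must be singletons; exclude missing members first")
  }
  as.numeric(a == b)
}

#' Pairwise overlap for multiple-choice selections
#'
#' Scores the overlap of two non-empty option sets on a 0-1 scale. The
#' default is the Jaccard index |a
#' \eqn{\cap}{n} b| / |a \eqn{\cup}{u} b|, the canonical
#' proportion-of-overlapping-responses statistic; the Dice coefficient
#' 2|a\eqn{\cap}{n}b|/(|a|+|b|) and the overlap coefficient
#' |a\eqn{\cap}{n}b|/min(|a|,|b|) are available as alternatives. All three
#' are symmetric and equal 1 exactly for identical sets (the overlap
#' coefficient also reaches 1 for nested sets).
#'
#' @param a,b Character vectors of selected options (non-empty).
#' @param metric `"jaccard"` (default), `"dice"`, or `"overlap"`.
#' @return Score in \[0, 1\].
#' @examples
#' pair_overlap_multi(c("A", "B"), c("B", "C"))            # 1/3
#' pair_overlap_multi(c("A", "B"), c("B", "C"), "dice")    # 1/2
#' pair_overlap_multi(c("A", "B"), c("B", "C"), "overlap") # 1/2
#' @export
pair_overlap_multi <- function(a, b, metric = c("jaccard", "dice", "overlap")) {
  metric <- match.arg(metric)
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("empty selection: exclude missing members before pairing")
  }
  i <- length(intersect(a, b))
  switch(metric,
    jaccard = i / length(union(a, b)),
    dice = 2 * i / (length(a) + length(b)),
    overlap = i / min(length(a), length(b))
  )
}

#' Team similarity on one item
#'
#' The item-level similarity of k responding members is the mean pair score
#' over all choose(k, 2) unordered member pairs. For single-choice items this
#' equals the number of agreeing pairs divided by the maximum possible number
#' of agreements; for multiple-choice items the pair score is the chosen
#' overlap metric.
#'
#' @param selections List of character vectors, one per responding member.
#'   Empty selections are dropped (indistinguishable from missing).
#' @param mode `"single"` or `"multi"`.
#' @param metric Overlap metric for multi mode; see [pair_overlap_multi()].
#' @return Score in \[0, 1\], or `NA` when fewer than 2 members responded.
#' @examples
#' item_similarity(list("X", "X", "Y"), "single")  # 1/3
#' item_similarity(list(c("A", "B"), c("B", "C"), c("A", "B")), "multi")
#' @export
item_similarity <- function(selections, mode = c("single", "multi"),
                            metric = c("jaccard", "dice", "overlap")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  selections <- selections[lengths(selections) > 0L]
  k <- length(selections)
  if (k < 2L) return(NA_real_)
  if (mode == "single" && any(lengths(selections) != 1L)) {
    stop("single-choice selections must be singletons")
  }
  tot <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      tot <- tot + if (mode == "single") {
        pair_agreement_single(selections[[i]], selections[[j]])
      } else {
        pair_overlap_multi(selections[[i]], selections[[j]], metric)
      }
    }
  }
  tot / choose(k, 2)
}

# popcounts of 0:(2^16-1), built lazily once per session
.pc_env <- new.env(parent = emptyenv())
.popcount <- function(x) {
  if (is.null(.pc_env$tab)) {
    tab <- integer(65536L)
    for (b in 0:15) tab[bitwAnd(0:65535, bitwShiftL(1L, b)) > 0L] <-
        tab[bitwAnd(0:65535, bitwShiftL(1L, b)) > 0L] + 1L
    .pc_env$tab <- tab
  }
  .pc_env$tab[x + 1L]
}

# mean pairwise score over a vector of selection bitmasks (all non-zero)
.pair_mean_masks <- function(masks, metric) {
  k <- length(masks)
  a <- rep(masks[-k], times = (k - 1L):1L)
  b <- masks[sequence((k - 1L):1L, from = 2:k)]
  i <- .popcount(bitwAnd(a, b))
  pa <- .popcount(a); pb <- .popcount(b)
  s <- switch(metric,
    jaccard = i / (pa + pb - i),
    dice = 2 * i / (pa + pb),
    overlap = i / pmin(pa, pb)
  )
  mean(s)
}

#' Score every team at every time point
#'
#' Computes item-, domain- and total-level similarity for each (team, time)
#' cell of a study. Members missing an item are excluded from that item's
#' pair set only; an item with fewer than two responders in a cell is
#' undefined (`NA`) and excluded from aggregation. The domain score is the
#' unweighted mean of its defined item scores and the total is the
#' item-count-weighted mean of the domain scores — algebraically the plain
#' mean over all defined item scores.
#'
#' @param study An [smm_study()].
#' @param metric Overlap metric for multiple-choice items; see
#'   [pair_overlap_multi()].
#' @return A data frame of class `smm_scores` with one row per (team, time):
#'   columns `group`, `team_id`, `time`, `task_responsibility`,
#'   `communication`, `total` (all proportions in \[0, 1\]), `n_members`,
#'   `n_items_scored`. Deterministic and invariant to row, member and team
#'   ordering. The per-item score matrix is attached as attribute
#'   `item_scores`.
#' @examples
#' study <- simulate_study(simulation_config(n_teams = c(3, 3), seed = 1))
#' head(score_study(study))
#' @export
score_study <- function(study, metric = c("jaccard", "dice", "overlap")) {
  stopifnot(inherits(study, "smm_study"))
  metric <- match.arg(metric)
  r <- study$responses
  qit <- study$questionnaire$items
  mode_of <- stats::setNames(qit$response_mode, qit$item_id)
  dom_of <- stats::setNames(qit$domain, qit$item_id)

  key <- paste0(r$team_id, "\r", r$time, "\r", r$item_id)
  is_single <- mode_of[r$item_id] == "single"

  scores <- numeric(0)

  ## single-choice: per cell, sum C(n_o, 2) over options / C(k, 2)
  if (any(is_single)) {
    ks <- key[is_single]
    ko <- paste0(ks, "\r", r$option[is_single])
    f <- factor(ko)
    n_o <- tabulate(f)
    lev_key <- sub("\r[^\r]*$", "", levels(f))
    agree <- rowsum(choose(n_o, 2), lev_key)
    k <- rowsum(n_o, lev_key)
    s <- ifelse(k >= 2L, agree / choose(k, 2), NA_real_)
    scores <- c(scores, stats::setNames(as.numeric(s), rownames(agree)))
  }

  ## multiple-choice: bitmask per member, mean pairwise overlap per cell
  if (any(!is_single)) {
    rm_ <- r[!is_single, , drop = FALSE]
    km <- key[!is_single]
    opts <- study$questionnaire$options
    m_of <- stats::setNames(qit$n_options, qit$item_id)
    use_mask <- all(m_of[unique(rm_$item_id)] <= 16L)
    cellmem <- paste0(km, "\r", rm_$member_id)
    if (use_mask) {
      oidx <- integer(nrow(rm_))
      for (it in unique(rm_$item_id)) {
        sel <- rm_$item_id == it
        oidx[sel] <- match(rm_$option[sel], opts[[it]])
      }
      bit <- bitwShiftL(1L, oidx - 1L)
      masks <- rowsum(bit, cellmem)
      mask_key <- sub("\r[^\r]*$", "", rownames(masks))
      per_cell <- split(as.integer(masks), mask_key)
      s <- vapply(per_cell, function(ms) {
        if (length(ms) < 2L) NA_real_ else .pair_mean_masks(ms, metric)
      }, 0)
    } else {
      sel_by_mem <- split(rm_$option, cellmem)
      mem_key <- sub("\r[^\r]*$", "", names(sel_by_mem))
      per_cell <- split(sel_by_mem, mem_key)
      s <- vapply(per_cell, function(sels) {
        item_similarity(unname(sels), "multi", metric)
      }, 0)
    }
    scores <- c(scores, s)
  }

  parts <- do.call(rbind, strsplit(names(scores), "\r", fixed = TRUE))
  cells <- data.frame(
    team_id = parts[, 1L], time = parts[, 2L], item_id = parts[, 3L],
    score = as.numeric(scores), stringsAsFactors = FALSE
  )
  cells$domain <- dom_of[cells$item_id]

  tt <- paste0(cells$team_id, "\r", cells$time)
  agg <- function(sub) {
    by_dom <- tapply(sub$score, sub$domain, mean, na.rm = TRUE)
    def <- !is.na(sub$score)
    c(
      task_responsibility = unname(by_dom["task_responsibility"]),
      communication = unname(by_dom["communication"]),
      total = if (any(def)) mean(sub$score[def]) else NA_real_,
      n_items_scored = sum(def)
    )
  }
  sp <- split(cells, tt)
  mat <- t(vapply(sp, agg, numeric(4)))
  parts2 <- do.call(rbind, strsplit(rownames(mat), "\r", fixed = TRUE))

  nmem_key <- paste0(r$team_id, "\r", r$time)
  nmem <- vapply(split(r$member_id, nmem_key), function(m) length(unique(m)), 0L)

  out <- data.frame(
    group = unname(study$groups[parts2[, 1L]]),
    team_id = parts2[, 1L],
    time = parts2[, 2L],
    task_responsibility = mat[, "task_responsibility"],
    communication = mat[, "communication"],
    total = mat[, "total"],
    n_members = unname(nmem[rownames(mat)]),
    n_items_scored = as.integer(mat[, "n_items_scored"]),
    stringsAsFactors = FALSE
  )
  out$time <- factor(out$time, levels = study$time_points)
  out <- out[order(out$group, out$team_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "item_scores") <- cells[order(cells$team_id, cells$time, cells$item_id),
                                    c("team_id", "time", "item_id", "domain", "score")]
  class(out) <- c("smm_scores", "data.frame")
  out
}

#' Score a single team at one time point
#'
#' Convenience wrapper around the study scorer for one (team, time) cell.
#'
#' @param study An [smm_study()].
#' @param team_id,time_point The cell to score.
#' @inheritParams score_study
#' @return List with `team_id`, `time`, `item_scores` (named numeric, `NA`
#'   for unscorable items), `domain_scores`, and `total`.
#' @export
score_team <- function(study, team_id, time_point,
                       metric = c("jaccard", "dice", "overlap")) {
  metric <- match.arg(metric)
  stopifnot(team_id %in% names(study$groups), time_point %in% study$time_points)
  tab <- score_study(study, metric = metric)
  items <- attr(tab, "item_scores")
  it <- items[items$team_id == team_id & items$time == time_point, , drop = FALSE]
  row <- tab[tab$team_id == team_id & tab$time == time_point, , drop = FALSE]
  list(
    team_id = team_id,
    time = time_point,
    item_scores = stats::setNames(it$score, it$item_id),
    domain_scores = c(
      task_responsibility = row$task_responsibility,
      communication = row$communication
    ),
    total = row$total
  )
}

#' Percentage report of a score table
#'
#' Converts the proportion-valued score columns to percentages rounded to
#' `digits` decimal places, mirroring how team similarity is conventionally
#' reported.
#'
#' @param scores An `smm_scores` data frame from [score_study()].
#' @param digits Decimal places (default 2).
#' @return A plain data frame with percentage-scale score columns.
#' @export
scores_as_percent <- function(scores, digits = 2L) {
  out <- as.data.frame(scores)
  for (cl in c("task_responsibility", "communication", "total")) {
    out[[cl]] <- round(100 * out[[cl]], digits)
  }
  out
}
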