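#' Expected pairwise agreement under the modal-response model
#'
#' In the generator each team holds one canonical ("modal") answer per
#' single-choice item; every member independently selects it with adherence
#' probability c and otherwise picks uniformly among the remaining m - 1
#' options. Two members then agree with probability
#' c^2 + (1 - c)^2 / (m - 1).
#'
#' @param c Adherence probability in \[0, 1\]; vectorised.
#' @param m Number of response options (>= 2).
#' @return Expected pair agreement in \[1/m, 1\] for c >= 1/m.
#' @examples
#' expected_agreement_single(0.6, 5)  # 0.40
#' expected_agreement_single(1, 7)    # 1
#' @export
expected_agreement_single <- function(c, m) {
  stopifnot(m >= 2, all(c >= 0), all(c <= 1))
  c^2 + (1 - c)^2 / (m - 1)
}

#' Invert expected agreement to an adherence probability
#'
#' Solves expected_agreement_single(c, m) = a on the monotone branch
#' c in \[1/m, 1\] (closed form of the quadratic), so that a target mean
#' similarity can be translated into a generator setting.
#'
#' @param a Target expected agreement, in \[1/m, 1\].
#' @param m Number of response options.
#' @return Adherence c in \[1/m, 1\].
#' @examples
#' invert_agreement(0.40, 5)  # 0.6
#' expected_agreement_single(invert_agreement(0.73, 5), 5)
#' @export
invert_agreement <- function(a, m) {
  stopifnot(m >= 2)
  if (any(a < 1 / m - 1e-12) || any(a > 1 + 1e-12)) {
    stop("target agreement must lie in [1/m, 1]")
  }
  a <- pmin(pmax(a, 1 / m), 1)
  (1 + sqrt(pmax(0, (m - 1) * (m * a - 1)))) / m
}

#' Exact expected pairwise overlap under the inclusion model
#'
#' For multiple-choice items the generator gives each team a canonical
#' subset of s options; a member includes each canonical option with
#' probability `p_in` and each of the other m - s options with probability
#' `p_out`, independently. The expected pairwise overlap of two such
#' members, conditional on both selections being non-empty (empty
#' selections count as missing and are excluded from pairing), is computed
#' exactly by enumerating all 2^m selection subsets.
#'
#' @param p_in,p_out Inclusion probabilities in \[0, 1\].
#' @param s Canonical subset size (1 <= s <= m).
#' @param m Number of options (2 <= m <= 12).
#' @param metric Overlap metric; see [pair_overlap_multi()].
#' @return Expected pair score in \[0, 1\].
#' @export
expected_overlap_multi <- function(p_in, p_out, s, m,
                                   metric = c("jaccard", "dice", "overlap")) {
  metric <- match.arg(metric)
  stopifnot(m >= 2, m <= 12, s >= 1, s <= m,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  masks <- 0:(2^m - 1)
  canon <- 2^s - 1L                      # canonical = first s bits, wlog
  cb <- .popcount(bitwAnd(masks, canon))
  ob <- .popcount(masks) - cb
  pr <- p_in^cb * (1 - p_in)^(s - cb) * p_out^ob * (1 - p_out)^(m - s - ob)
  nz <- masks[masks > 0L]
  pnz <- pr[masks > 0L] / sum(pr[masks > 0L])
  ii <- rep(nz, each = length(nz)); jj <- rep(nz, length(nz))
  inter <- .popcount(bitwAnd(ii, jj))
  pi_ <- .popcount(ii); pj <- .popcount(jj)
  sc <- switch(metric,
    jaccard = inter / (pi_ + pj - inter),
    dice = 2 * inter / (pi_ + pj),
    overlap = inter / pmin(pi_, pj)
  )
  sum(rep(pnz, each = length(pnz)) * rep(pnz, length(pnz)) * sc)
}

#' Invert expected overlap to an inclusion probability
#'
#' Finds `p_in` such that [expected_overlap_multi()] hits a target value,
#' holding `p_out`, `s`, `m` fixed (monotone in `p_in` on
#' \[`p_out`, 1\]; solved numerically).
#'
#' @param target Target expected overlap.
#' @inheritParams expected_overlap_multi
#' @return Inclusion probability `p_in`.
#' @export
invert_overlap <- function(target, p_out, s, m,
                           metric = c("jaccard", "dice", "overlap")) {
  metric <- match.arg(metric)
  f <- function(p) expected_overlap_multi(p, p_out, s, m, metric) - target
  lo <- f(max(p_out, 1e-6)); hi <- f(1)
  if (lo > 0 || hi < 0) {
    stop(sprintf("target overlap %.3f not attainable with p_out = %.3f, s = %d, m = %d",
                 target, p_out, s, m))
  }
  stats::uniroot(f, c(max(p_out, 1e-6), 1), tol = 1e-10)$root
}

## Published group x time domain means (proportions) used to calibrate the
## generator's default convergence levels.
.default_targets <- function() {
  list(
    task = rbind(checklist = c(pre = 0.6127, post = 0.7371),
                 algorithm = c(pre = 0.6226, post = 0.7144)),
    comm = rbind(checklist = c(pre = 0.8078, post = 0.8258),
                 algorithm = c(pre = 0.8042, post = 0.8238))
  )
}

#' Configure the team-response generator
#'
#' Builds a validated configuration for [simulate_study()]. By default it
#' emulates the study design: two training groups of 15 and 14 teams, team
#' sizes uniform on 5-9, the 54-item instrument of
#' [default_questionnaire()], and per-group pre/post convergence levels
#' calibrated so expected domain similarities match the published
#' descriptives (task responsibility ~0.61 pre rising to ~0.72-0.74 post,
#' communication ~0.81 pre to ~0.83 post).
#'
#' Convergence can be set two ways: via `targets` (group x time expected
#' domain similarities, inverted internally to model parameters) or
#' directly via `adherence` and `p_in`. The five multiple-choice
#' task-responsibility items share the communication inclusion parameters,
#' so the single-choice adherence is calibrated to make the 26-item task
#' domain mean hit its target.
#'
#' @param n_teams Integer vector of teams per group (default `c(15, 14)`);
#'   names become group labels (default `checklist`, `algorithm`).
#' @param team_size Integer range `c(min, max)` of members per team,
#'   drawn uniformly (default `c(5, 9)`).
#' @param questionnaire A [questionnaire_spec()]; default the 54-item
#'   instrument.
#' @param targets Optional list with matrices `task` and `comm`
#'   (groups x times) of expected domain similarity; default the published
#'   levels.
#' @param adherence,p_in Optional groups x times matrices overriding the
#'   calibrated single-choice adherence / multi-choice canonical inclusion
#'   probability.
#' @param p_out Inclusion probability for non-canonical options (default
#'   0.05).
#' @param s_canon Canonical subset size for multiple-choice items
#'   (default 2).
#' @param time_points Time point labels (default `c("pre", "post")`).
#' @param seed Integer seed; fully determines the simulated dataset.
#' @return List of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(seed = 7)
#' cfg$adherence
#' @export
simulation_config <- function(n_teams = c(checklist = 15L, algorithm = 14L),
                              team_size = c(5L, 9L),
                              questionnaire = default_questionnaire(),
                              targets = NULL,
                              adherence = NULL, p_in = NULL,
                              p_out = 0.05, s_canon = 2L,
                              time_points = c("pre", "post"),
                              seed = NULL) {
  stopifnot(inherits(questionnaire, "questionnaire_spec"),
            length(n_teams) >= 1L, all(n_teams >= 2L),
            length(team_size) == 2L, team_size[1L] >= 2L,
            team_size[2L] >= team_size[1L],
            p_out >= 0, p_out <= 1, s_canon >= 1L,
            length(time_points) >= 2L)
  if (is.null(names(n_teams))) {
    names(n_teams) <- if (length(n_teams) == 2L) c("checklist", "algorithm")
                      else paste0("group", seq_along(n_teams))
  }
  groups <- names(n_teams)
  it <- questionnaire$items
  m_single <- it$n_options[it$response_mode == "single"]
  m_multi <- it$n_options[it$response_mode == "multi"]
  if (length(m_multi) && any(s_canon >= m_multi)) {
    stop("s_canon must be smaller than every multiple-choice item's option count")
  }

  if (is.null(targets)) targets <- .default_targets()
  dimfix <- function(x) {
    x <- as.matrix(x)
    if (!all(groups %in% rownames(x))) {
      stopifnot(nrow(x) == length(groups))
      rownames(x) <- groups
    }
    colnames(x) <- time_points[seq_len(ncol(x))]
    x[groups, , drop = FALSE]
  }

  if (is.null(p_in)) {
    if (!length(m_multi)) {
      p_in <- matrix(0, length(groups), length(time_points),
                     dimnames = list(groups, time_points))
    } else {
      tc <- dimfix(targets$comm)
      mm <- m_multi[1L]
      p_in <- apply(tc, c(1, 2), function(a) invert_overlap(a, p_out, s_canon, mm))
    }
  } else {
    p_in <- dimfix(p_in)
  }
  if (is.null(adherence)) {
    if (!length(m_single)) {
      adherence <- matrix(1, length(groups), length(time_points),
                          dimnames = list(groups, time_points))
    } else {
      tt <- dimfix(targets$task)
      tc <- dimfix(targets$comm)
      n_ts <- sum(it$response_mode == "single" & it$domain == "task_responsibility")
      n_tm <- sum(it$response_mode == "multi" & it$domain == "task_responsibility")
      ## task domain mean = (n_ts * a_single + n_tm * a_multi) / (n_ts + n_tm)
      a_single <- ((n_ts + n_tm) * tt - n_tm * tc) / n_ts
      ms <- m_single[1L]
      adherence <- apply(a_single, c(1, 2), invert_agreement, m = ms)
    }
  } else {
    adherence <- dimfix(adherence)
  }
  stopifnot(all(p_in >= 0), all(p_in <= 1),
            all(adherence >= 0), all(adherence <= 1))
  if (length(m_single) && any(adherence < 1 / min(m_single) - 1e-9)) {
    stop("adherence below chance level 1/m; expected agreement would be non-monotone")
  }

  structure(
    list(
      n_teams = as.integer(n_teams), groups = groups,
      team_size = as.integer(team_size),
      questionnaire = questionnaire,
      adherence = adherence, p_in = p_in,
      p_out = p_out, s_canon = as.integer(s_canon),
      time_points = time_points, seed = seed
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:", sum(x$n_teams), "teams (",
      paste(sprintf("%s=%d", x$groups, x$n_teams), collapse = ", "),
      "), sizes", paste(x$team_size, collapse = "-"), "\n")
  cat("single-choice adherence:\n"); print(round(x$adherence, 4))
  cat("multi-choice p_in (p_out =", x$p_out, ", s =", x$s_canon, "):\n")
  print(round(x$p_in, 4))
  invisible(x)
}

#' Simulate a team questionnaire study
#'
#' Draws a full study dataset from the modal-response model: each team gets
#' one canonical option (single-choice) or canonical subset (multiple
#' choice) per item, fixed across time; members respond independently given
#' the team canon, with group- and time-specific adherence/inclusion
#' parameters implementing the training effect. Multiple-choice members
#' whose draw selects no option are recorded as missing for that item.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A validated [smm_study()]. Identical seeds give identical
#'   datasets.
#' @examples
#' st <- simulate_study(simulation_config(n_teams = c(4, 4), seed = 1))
#' st
#' @export
simulate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  q <- config$questionnaire
  it <- q$items
  groups <- config$groups
  times <- config$time_points

  n_all <- sum(config$n_teams)
  team_ids <- sprintf("T%03d", seq_len(n_all))
  team_group <- rep(groups, config$n_teams)
  size_range <- seq(config$team_size[1L], config$team_size[2L])
  sizes <- size_range[sample.int(length(size_range), n_all, replace = TRUE)]

  members <- data.frame(
    team = rep(seq_len(n_all), sizes),
    member_id = unlist(lapply(sizes, function(k) sprintf("M%d", seq_len(k)))),
    stringsAsFactors = FALSE
  )
  nm <- nrow(members)

  single_idx <- which(it$response_mode == "single")
  multi_idx <- which(it$response_mode == "multi")

  ## team canon: option index per (team, item) for single items;
  ## canonical subset (first by random permutation) for multi items
  canon_single <- matrix(0L, n_all, length(single_idx))
  for (j in seq_along(single_idx)) {
    canon_single[, j] <- sample.int(it$n_options[single_idx[j]], n_all, replace = TRUE)
  }
  canon_multi <- vector("list", length(multi_idx))   # [[j]]: n_all x s matrix
  for (j in seq_along(multi_idx)) {
    mj <- it$n_options[multi_idx[j]]
    canon_multi[[j]] <- t(vapply(seq_len(n_all),
                                 function(i) sample.int(mj, config$s_canon),
                                 integer(config$s_canon)))
  }

  g_idx <- match(team_group, groups)
  out <- vector("list", 2L * (length(single_idx) + length(multi_idx)))
  oi <- 0L

  for (tp in seq_along(times)) {
    cvec <- config$adherence[, times[tp]][g_idx[members$team]]    # per member
    ## single-choice items
    for (j in seq_along(single_idx)) {
      mj <- it$n_options[single_idx[j]]
      canon <- canon_single[members$team, j]
      pick_canon <- stats::runif(nm) < cvec
      alt <- sample.int(mj - 1L, nm, replace = TRUE)
      alt <- alt + (alt >= canon)
      opt <- ifelse(pick_canon, canon, alt)
      oi <- oi + 1L
      out[[oi]] <- data.frame(
        team = members$team, member_id = members$member_id,
        time = times[tp], item_id = it$item_id[single_idx[j]],
        option = q$options[[single_idx[j]]][opt],
        stringsAsFactors = FALSE
      )
    }
    ## multiple-choice items
    pin <- config$p_in[, times[tp]][g_idx[members$team]]
    for (j in seq_along(multi_idx)) {
      mj <- it$n_options[multi_idx[j]]
      cm <- canon_multi[[j]][members$team, , drop = FALSE]       # nm x s
      incl <- matrix(FALSE, nm, mj)
      u <- matrix(stats::runif(nm * mj), nm, mj)
      p <- matrix(config$p_out, nm, mj)
      p[cbind(rep(seq_len(nm), config$s_canon), as.vector(cm))] <- rep(pin, config$s_canon)
      incl <- u < p
      sel <- which(incl, arr.ind = TRUE)
      oi <- oi + 1L
      out[[oi]] <- data.frame(
        team = members$team[sel[, 1L]], member_id = members$member_id[sel[, 1L]],
        time = times[tp], item_id = it$item_id[multi_idx[j]],
        option = q$options[[multi_idx[j]]][sel[, 2L]],
        stringsAsFactors = FALSE
      )
    }
  }
  resp <- do.call(rbind, out[seq_len(oi)])
  resp$team_id <- team_ids[resp$team]
  resp$group <- team_group[resp$team]
  resp <- resp[c("group", "team_id", "member_id", "time", "item_id", "option")]
  smm_study(resp, q, time_points = times)
}
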