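#' Two-way mixed repeated-measures ANOVA for team-level outcomes
#'
#' Fits the classical mixed (split-plot) design with one between-unit factor
#' (training group) and one within-unit factor (time), units being teams.
#' The sums of squares use the unweighted-means (Type III-style) solution,
#' so with unequal group sizes each effect tests contrasts of unweighted
#' cell means; for two groups this coincides with the SPSS/SAS Type III
#' decomposition. Tests are F ratios against the error of the effect's own
#' stratum: group against teams-within-groups, time and time x group against
#' time x teams-within-groups. Effect sizes are partial eta squared,
#' SS_effect / (SS_effect + SS_error_of_stratum).
#'
#' @param formula `outcome ~ group * time` (or `outcome ~ time` for a
#'   single-group pre/post design, in which case the time test is the paired
#'   t test in F form).
#' @param data Data frame in long form: one row per team per time point,
#'   e.g. the output of [score_study()].
#' @param team Name of the column identifying the team (default
#'   `"team_id"`).
#' @return An object of class `smm_anova` with components `table` (effect,
#'   df, F, p, partial eta squared), `strata` (error SS and df), `cell_means`,
#'   `varcomp`, and the model frame. Methods: [print.smm_anova()],
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `simulate`,
#'   `plot`, `as.data.frame`.
#' @details Every team must be observed at every time point: the design
#'   excluded incomplete teams, and this fit requires the caller to do the
#'   same (an informative error lists offending teams). Each group needs at
#'   least two teams. If the within-stratum error is exactly zero (possible
#'   on degenerate synthetic data) the affected F is `Inf` with p = 0 and
#'   the result carries a `zero_variance` flag rather than failing.
#' @examples
#' study <- simulate_study(simulation_config(n_teams = c(8, 7), seed = 42))
#' sc <- score_study(study)
#' fit <- smm_anova(total ~ group * time, data = sc)
#' fit
#' summary(fit)
#' @export
smm_anova <- function(formula, data, team = "team_id") {
  vars <- all.vars(formula)
  outcome <- vars[1L]
  if (!team %in% names(data)) stop("team column '", team, "' not found")
  rhs <- vars[-1L]
  if (!length(rhs) || length(rhs) > 2L) {
    stop("formula must be outcome ~ group * time or outcome ~ time")
  }
  time_var <- rhs[length(rhs)]
  group_var <- if (length(rhs) == 2L) rhs[1L] else NULL

  y <- as.numeric(data[[outcome]])
  tm <- factor(data[[time_var]])
  id <- factor(data[[team]])
  g <- if (is.null(group_var)) factor(rep("all", length(y))) else factor(data[[group_var]])
  if (anyNA(y)) stop("outcome contains missing values; exclude incomplete teams first")

  t_lev <- levels(tm); a_lev <- levels(g)
  t_n <- length(t_lev); a_n <- length(a_lev)
  if (t_n < 2L) stop("need at least two time points")

  ## completeness: every team at every time, once
  tab <- table(id, tm)
  bad <- rownames(tab)[apply(tab, 1L, function(z) any(z != 1L))]
  if (length(bad)) {
    stop("team(s) without exactly one observation per time point (exclude them): ",
         paste(bad, collapse = ", "))
  }
  g_of_id <- tapply(as.character(g), id, unique)
  if (any(lengths(g_of_id) > 1L)) stop("a team appears in more than one group")
  g_of_id <- factor(vapply(g_of_id, `[[`, "", 1L), levels = a_lev)
  n_g <- table(g_of_id)
  if (any(n_g < 2L)) {
    stop("fewer than 2 teams in group(s): ",
         paste(names(n_g)[n_g < 2L], collapse = ", "))
  }
  N <- length(levels(id))

  ## cell means (unweighted), subject means
  cell <- tapply(y, list(g, tm), mean)              # a x t
  subj_mean <- tapply(y, id, mean)
  gm_u <- mean(cell)                                # unweighted grand mean
  row_m <- rowMeans(cell)                           # per-group means
  col_m <- colMeans(cell)                           # per-time (unweighted)
  n_tilde <- a_n / sum(1 / as.numeric(n_g))         # harmonic mean group size

  ss_group <- t_n * n_tilde * sum((row_m - gm_u)^2)
  ss_subj <- t_n * sum((subj_mean - row_m[g_of_id])^2)
  ss_time <- a_n * n_tilde * sum((col_m - gm_u)^2)
  inter <- sweep(sweep(cell, 1L, row_m), 2L, col_m) + gm_u
  ss_int <- n_tilde * sum(inter^2)
  fit_full <- cell[cbind(as.integer(g), as.integer(tm))] +
    (subj_mean[id] - row_m[g_of_id][as.integer(id)])
  ss_err_w <- sum((y - fit_full)^2)

  ## floating-point guard: an error SS that is numerically zero relative to
  ## its stratum is treated as exactly zero (degenerate inputs)
  tot_b <- ss_group + ss_subj
  tot_w <- ss_time + ss_int + ss_err_w
  if (tot_b > 0 && ss_subj <= 1e-10 * tot_b) ss_subj <- 0
  if (tot_w > 0 && ss_err_w <= 1e-10 * tot_w) ss_err_w <- 0

  df_grp <- a_n - 1L
  df_subj <- N - a_n
  df_time <- t_n - 1L
  df_int <- (a_n - 1L) * (t_n - 1L)
  df_err_w <- (N - a_n) * (t_n - 1L)

  fstat <- function(ss_e, df_e, ss_r, df_r) {
    ss_e <- unname(ss_e); df_e <- unname(df_e)
    ss_r <- unname(ss_r); df_r <- unname(df_r)
    ms_r <- ss_r / df_r
    if (ms_r == 0) {
      if (ss_e == 0) c(F = NaN, p = NaN) else c(F = Inf, p = 0)
    } else {
      F <- (ss_e / df_e) / ms_r
      c(F = F, p = stats::pf(F, df_e, df_r, lower.tail = FALSE))
    }
  }
  eff <- list(
    group = c(ss = ss_group, df = df_grp, err_ss = ss_subj, err_df = df_subj),
    time = c(ss = ss_time, df = df_time, err_ss = ss_err_w, err_df = df_err_w),
    `time:group` = c(ss = ss_int, df = df_int, err_ss = ss_err_w, err_df = df_err_w)
  )
  if (a_n == 1L) eff <- eff["time"]
  rows <- lapply(eff, function(e) {
    fp <- fstat(e["ss"], e["df"], e["err_ss"], e["err_df"])
    data.frame(
      SS = unname(e["ss"]), df = unname(e["df"]), df_error = unname(e["err_df"]),
      F = unname(fp["F"]), p = unname(fp["p"]),
      eta_p_sq = unname(e["ss"] / (e["ss"] + e["err_ss"])),
      row.names = NULL
    )
  })
  table <- cbind(effect = names(eff), do.call(rbind, rows))
  rownames(table) <- NULL

  ms_subj <- ss_subj / df_subj
  ms_err <- ss_err_w / df_err_w
  varcomp <- c(
    team = max(0, (ms_subj - ms_err) / t_n),
    residual = ms_err
  )

  structure(
    list(
      table = table,
      strata = data.frame(
        stratum = c("teams within groups", "time x teams within groups"),
        SS = c(ss_subj, ss_err_w), df = c(df_subj, df_err_w)
      ),
      cell_means = cell,
      varcomp = varcomp,
      n_teams = as.numeric(n_g),
      zero_variance = ms_err == 0,
      outcome = outcome, group_var = group_var, time_var = time_var,
      team_var = team,
      frame = data.frame(y = y, group = g, time = tm, team = id),
      call = match.call()
    ),
    class = "smm_anova"
  )
}

#' @export
print.smm_anova <- function(x, digits = 4L, ...) {
  cat("Mixed repeated-measures ANOVA (unweighted means)\n")
  cat("outcome:", x$outcome, "  teams:", sum(x$n_teams),
      if (!is.null(x$group_var)) paste0("(", paste(x$n_teams, collapse = "/"), ")"),
      "\n\n")
  tab <- x$table
  tab$df <- sprintf("%d, %d", as.integer(tab$df), as.integer(tab$df_error))
  tab$df_error <- NULL
  tab$SS <- signif(tab$SS, digits)
  tab$F <- round(tab$F, 2)
  tab$p <- format.pval(tab$p, digits = 3, eps = 1e-3)
  tab$eta_p_sq <- round(tab$eta_p_sq, 2)
  print(tab, row.names = FALSE)
  if (isTRUE(x$zero_variance)) {
    cat("note: within-team error variance is exactly zero; F is infinite\n")
  }
  invisible(x)
}

#' @export
summary.smm_anova <- function(object, ...) {
  object$descriptives <- do.call(rbind, lapply(levels(object$frame$group), function(gl) {
    do.call(rbind, lapply(levels(object$frame$time), function(tl) {
      yy <- object$frame$y[object$frame$group == gl & object$frame$time == tl]
      data.frame(group = gl, time = tl, n = length(yy),
                 mean = mean(yy), sd = stats::sd(yy))
    }))
  }))
  class(object) <- c("summary.smm_anova", class(object))
  object
}

#' @export
print.summary.smm_anova <- function(x, ...) {
  NextMethod()
  cat("\nCell descriptives:\n")
  d <- x$descriptives
  d$mean <- round(d$mean, 4); d$sd <- round(d$sd, 4)
  print(d, row.names = FALSE)
  cat("\nVariance components: team =", signif(x$varcomp["team"], 4),
      " residual =", signif(x$varcomp["residual"], 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.smm_anova <- function(x, ...) x$table

#' @export
coef.smm_anova <- function(object, ...) {
  cell <- object$cell_means
  gm <- mean(cell)
  list(
    grand_mean = gm,
    group = rowMeans(cell) - gm,
    time = colMeans(cell) - gm,
    interaction = sweep(sweep(cell, 1L, rowMeans(cell)), 2L, colMeans(cell)) + gm,
    cell_means = cell
  )
}

#' @export
fitted.smm_anova <- function(object, ...) {
  fr <- object$frame
  cell <- object$cell_means
  subj_mean <- tapply(fr$y, fr$team, mean)
  g_of_id <- tapply(as.character(fr$group), fr$team, `[`, 1L)
  row_m <- rowMeans(cell)
  as.numeric(cell[cbind(as.integer(fr$group), as.integer(fr$time))] +
    (subj_mean[fr$team] - row_m[g_of_id][as.integer(fr$team)]))
}

#' @export
residuals.smm_anova <- function(object, ...) {
  object$frame$y - fitted(object)
}

#' Population cell means for new group/time combinations
#'
#' @param object An [smm_anova()] fit.
#' @param newdata Data frame with the group and time columns used in the
#'   fit; omitted -> the full group x time grid.
#' @param ... Unused.
#' @return Numeric vector of predicted cell means.
#' @export
predict.smm_anova <- function(object, newdata = NULL, ...) {
  cell <- object$cell_means
  if (is.null(newdata)) {
    grid <- expand.grid(group = rownames(cell), time = colnames(cell),
                        KEEP.OUT.ATTRS = FALSE)
    return(cbind(grid, fit = cell[cbind(as.character(grid$group),
                                        as.character(grid$time))]))
  }
  gv <- if (is.null(object$group_var)) NULL else object$group_var
  gg <- if (is.null(gv)) rep(rownames(cell)[1L], nrow(newdata)) else as.character(newdata[[gv]])
  tt <- as.character(newdata[[object$time_var]])
  cell[cbind(gg, tt)]
}

#' Parametric simulation from a fitted team ANOVA
#'
#' Draws new team-level datasets from the fitted compound-symmetry model:
#' cell mean + normal team effect + normal residual, using the estimated
#' variance components.
#'
#' @param object An [smm_anova()] fit.
#' @param nsim Number of simulated datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` data frames shaped like the model frame.
#' @export
simulate.smm_anova <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  cell <- object$cell_means
  ids <- levels(fr$team)
  g_of_id <- factor(tapply(as.character(fr$group), fr$team, `[`, 1L),
                    levels = rownames(cell))
  lapply(seq_len(nsim), function(s) {
    u <- stats::rnorm(length(ids), 0, sqrt(object$varcomp["team"]))
    names(u) <- ids
    mu <- cell[cbind(as.integer(g_of_id[fr$team]), as.integer(fr$time))]
    data.frame(
      team = fr$team, group = fr$group, time = fr$time,
      y = mu + u[as.character(fr$team)] +
        stats::rnorm(nrow(fr), 0, sqrt(object$varcomp["residual"]))
    )
  })
}

#' @export
plot.smm_anova <- function(x, ...) {
  cell <- x$cell_means
  t_n <- ncol(cell)
  graphics::matplot(seq_len(t_n), t(cell), type = "b", pch = 19, lty = 1,
          xaxt = "n", xlab = x$time_var, ylab = x$outcome,
          main = "Group x time cell means", ...)
  graphics::axis(1, at = seq_len(t_n), labels = colnames(cell))
  graphics::legend("topleft", legend = rownames(cell), col = seq_len(nrow(cell)),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Partial eta squared from an F statistic
#'
#' Converts a reported F with its degrees of freedom into partial eta
#' squared via F df1 / (F df1 + df2), the algebraic equivalent of
#' SS_effect / (SS_effect + SS_error).
#'
#' @param f F statistic (>= 0); vectorised.
#' @param df_effect,df_error Degrees of freedom (>= 1).
#' @return Partial eta squared in \[0, 1\].
#' @examples
#' eta_p_sq_from_f(166.18, 1, 27)  # 0.86
#' @export
eta_p_sq_from_f <- function(f, df_effect, df_error) {
  if (any(f < 0) || any(df_effect < 1) || any(df_error < 1)) {
    stop("need f >= 0 and degrees of freedom >= 1")
  }
  f * df_effect / (f * df_effect + df_error)
}
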