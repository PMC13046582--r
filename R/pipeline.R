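#' Group x time descriptive statistics of a score table
#'
#' Mean (SD) per training group and time point for each outcome column, on
#' the percentage scale — the conventional descriptive layout for
#' team-similarity results.
#'
#' @param scores An `smm_scores` data frame (or anything with `group`,
#'   `time` and the outcome columns).
#' @param outcomes Score columns to summarise.
#' @param percent Report percentages (default) rather than proportions.
#' @return Data frame with columns `outcome`, `group`, `n`, one
#'   `mean_<time>` / `sd_<time>` pair per time point.
#' @export
describe_scores <- function(scores,
                            outcomes = c("task_responsibility", "communication", "total"),
                            percent = TRUE) {
  scale <- if (percent) 100 else 1
  times <- if (is.factor(scores$time)) levels(scores$time) else unique(scores$time)
  out <- list()
  for (oc in outcomes) {
    for (g in sort(unique(scores$group))) {
      row <- list(outcome = oc, group = g,
                  n = length(unique(scores$team_id[scores$group == g])))
      for (tp in times) {
        y <- scale * scores[[oc]][scores$group == g & scores$time == tp]
        row[[paste0("mean_", tp)]] <- mean(y, na.rm = TRUE)
        row[[paste0("sd_", tp)]] <- stats::sd(y[!is.na(y)])
      }
      out[[length(out) + 1L]] <- as.data.frame(row)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full analysis of a team score table
#'
#' Runs the descriptives plus one mixed repeated-measures ANOVA per outcome
#' (task responsibility, communication, total), mirroring the standard
#' reporting layout. Teams missing a time point are listed and excluded
#' with a warning before fitting.
#'
#' @inheritParams describe_scores
#' @return List of class `smm_analysis`: `descriptives`, `anova` (one
#'   [smm_anova()] per outcome), `excluded_teams`.
#' @export
analyze_scores <- function(scores,
                           outcomes = c("task_responsibility", "communication", "total")) {
  times <- if (is.factor(scores$time)) levels(scores$time) else unique(scores$time)
  cnt <- table(scores$team_id)
  incomplete <- names(cnt)[cnt < length(times)]
  if (length(incomplete)) {
    warning("excluding team(s) without all time points: ",
            paste(incomplete, collapse = ", "))
    scores <- scores[!(scores$team_id %in% incomplete), , drop = FALSE]
  }
  single_group <- length(unique(scores$group)) < 2L
  fits <- lapply(outcomes, function(oc) {
    f <- stats::reformulate(if (single_group) "time" else "group * time",
                            response = oc)
    smm_anova(f, data = scores)
  })
  names(fits) <- outcomes
  structure(
    list(descriptives = describe_scores(scores, outcomes),
         anova = fits, excluded_teams = incomplete),
    class = "smm_analysis"
  )
}

#' @export
print.smm_analysis <- function(x, digits = 2L, ...) {
  cat("== Descriptives (percent) ==\n")
  d <- x$descriptives
  num <- vapply(d, is.numeric, TRUE) & names(d) != "n"
  d[num] <- lapply(d[num], round, digits)
  print(d, row.names = FALSE)
  for (oc in names(x$anova)) {
    cat("\n== Mixed RM-ANOVA:", oc, "==\n")
    print(x$anova[[oc]])
  }
  if (length(x$excluded_teams)) {
    cat("\nexcluded incomplete teams:", paste(x$excluded_teams, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ANOVA report table across outcomes
#'
#' Stacks the effect tables of an [analyze_scores()] result into one data
#' frame (outcome, effect, df pair, F, p, partial eta squared), optionally
#' rounded to presentation precision.
#'
#' @param analysis An `smm_analysis` from [analyze_scores()].
#' @param digits Decimal places for F and eta (`NULL` = full precision).
#' @return Data frame.
#' @export
anova_report <- function(analysis, digits = NULL) {
  out <- do.call(rbind, lapply(names(analysis$anova), function(oc) {
    cbind(outcome = oc, analysis$anova[[oc]]$table)
  }))
  rownames(out) <- NULL
  if (!is.null(digits)) {
    out$F <- round(out$F, digits)
    out$eta_p_sq <- round(out$eta_p_sq, digits)
    out$p <- signif(out$p, 3)
    out$SS <- signif(out$SS, 6)
  }
  out
}

#' Pipeline steps: score, analyze, simulate, power
#'
#' Thin file-to-file wrappers over the package's functions, used by the
#' bundled command-line script (`inst/scripts/smm-pipeline.R`) and handy
#' for scripted reproducible runs. Each writes full-precision CSVs plus,
#' where noted, a rounded percentage report.
#'
#' @param responses_path CSV/TSV of long-format responses.
#' @param spec_path Questionnaire JSON/YAML; `NULL` uses
#'   [default_questionnaire()].
#' @param out_prefix Path prefix for output files.
#' @param metric Overlap metric for multiple-choice items.
#' @return `run_score()`: the `smm_scores` table (invisibly) after writing
#'   `<prefix>_scores.csv` (proportions, full precision) and
#'   `<prefix>_scores_report.csv` (percentages, 2 dp).
#' @export
run_score <- function(responses_path, spec_path = NULL, out_prefix = "smm",
                      metric = "jaccard") {
  spec <- if (is.null(spec_path)) default_questionnaire() else read_questionnaire(spec_path)
  study <- read_responses(responses_path, spec)
  flagged <- validate_study(study)
  if (nrow(flagged)) {
    message(nrow(flagged), " unscorable (team, time, item) cells; see validate_study()")
  }
  sc <- score_study(study, metric = metric)
  utils::write.csv(as.data.frame(sc), paste0(out_prefix, "_scores.csv"), row.names = FALSE)
  utils::write.csv(scores_as_percent(sc), paste0(out_prefix, "_scores_report.csv"),
                   row.names = FALSE)
  invisible(sc)
}

#' @param scores_path CSV written by [run_score()] (the full-precision
#'   variant), or an `smm_scores` data frame.
#' @rdname run_score
#' @return `run_analyze()`: the `smm_analysis` (invisibly) after writing
#'   `<prefix>_descriptives.csv`, `<prefix>_anova.csv` and a plain-text
#'   report `<prefix>_report.txt`.
#' @export
run_analyze <- function(scores_path, out_prefix = "smm") {
  sc <- if (is.data.frame(scores_path)) scores_path else {
    utils::read.csv(scores_path, stringsAsFactors = FALSE)
  }
  an <- analyze_scores(sc)
  utils::write.csv(an$descriptives, paste0(out_prefix, "_descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(anova_report(an), paste0(out_prefix, "_anova.csv"),
                   row.names = FALSE)
  txt <- paste0(out_prefix, "_report.txt")
  con <- file(txt, open = "wt", encoding = "UTF-8")
  sink(con); on.exit({ sink(); close(con) })
  print(an)
  invisible(an)
}

#' @param config A [simulation_config()] or path to a JSON/YAML file of
#'   its arguments.
#' @param seed Seed for the simulated dataset / experiment.
#' @rdname run_score
#' @return `run_simulate()`: the simulated [smm_study()] (invisibly) after
#'   writing `<prefix>_responses.csv` and `<prefix>_questionnaire.json`.
#' @export
run_simulate <- function(config = simulation_config(), out_prefix = "smm",
                         seed = NULL) {
  cfg <- .as_config(config)
  study <- simulate_study(cfg, seed = if (is.null(seed)) cfg$seed else seed)
  write_responses(study, paste0(out_prefix, "_responses.csv"))
  write_questionnaire(study$questionnaire, paste0(out_prefix, "_questionnaire.json"))
  invisible(study)
}

#' @param n_reps Replicates per configuration.
#' @param analysis Experiment kind; see [run_experiment()].
#' @rdname run_score
#' @return `run_power()`: the experiment table (invisibly) after writing
#'   `<prefix>_experiment.csv`.
#' @export
run_power <- function(config = simulation_config(), n_reps = 200L,
                      analysis = "power", out_prefix = "smm", seed = 1L) {
  cfg <- .as_config(config)
  res <- run_experiment(cfg, n_reps = n_reps, analysis = analysis, seed = seed)
  utils::write.csv(res, paste0(out_prefix, "_experiment.csv"), row.names = FALSE)
  invisible(res)
}

.as_config <- function(config) {
  if (inherits(config, "simulation_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    doc <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
    }
    args <- list()
    if (!is.null(doc$n_teams)) {
      args$n_teams <- unlist(doc$n_teams)
    }
    for (f in c("team_size", "p_out", "s_canon", "time_points", "seed")) {
      if (!is.null(doc[[f]])) args[[f]] <- unlist(doc[[f]])
    }
    for (f in c("adherence", "p_in")) {
      if (!is.null(doc[[f]])) args[[f]] <- do.call(rbind, lapply(doc[[f]], unlist))
    }
    if (!is.null(doc$questionnaire)) args$questionnaire <- read_questionnaire(doc$questionnaire)
    return(do.call(simulation_config, args))
  }
  stop("config must be a simulation_config or a file path")
}
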