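#' Assemble a validated study dataset
#'
#' A study dataset couples a questionnaire with long-format member responses
#' (one row per selected option) and a team-to-group allocation. A missing
#' response is the absence of rows for a (member, time, item) triple; there
#' is no explicit "none" answer category.
#'
#' @param responses Data frame with columns `group`, `team_id`, `member_id`,
#'   `time`, `item_id`, `option`. `time` must be one of the study time
#'   points (default `"pre"`/`"post"`).
#' @param questionnaire A [questionnaire_spec()] the responses must conform to.
#' @param time_points Character vector of allowed time points, ordered.
#' @return An object of class `smm_study`: list with `questionnaire`,
#'   `responses` (validated data frame), `groups` (named character vector
#'   team_id -> group), `team_sizes`, and `time_points`.
#' @details Validation rejects, with row-level diagnostics: unknown item or
#'   option identifiers, selections not among the item's options, more than
#'   one selected option for a single-choice (member, time, item), duplicated
#'   rows, teams allocated to more than one group, and teams with fewer than
#'   two responding members.
#' @examples
#' q <- questionnaire_spec("q1", "task_responsibility", "single",
#'                         list(c("teamleader", "anesthetist", "nurse")))
#' resp <- data.frame(
#'   group = "checklist", team_id = "T1", member_id = c("A", "B", "C"),
#'   time = "pre", item_id = "q1", option = "teamleader"
#' )
#' smm_study(resp, q)
#' @export
smm_study <- function(responses, questionnaire, time_points = c("pre", "post")) {
  stopifnot(inherits(questionnaire, "questionnaire_spec"))
  need <- c("group", "team_id", "member_id", "time", "item_id", "option")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("responses missing column(s): ", paste(miss, collapse = ", "))
  responses <- as.data.frame(responses)[need]
  for (cl in need) responses[[cl]] <- as.character(responses[[cl]])
  n <- nrow(responses)
  if (n == 0L) stop("no response rows")

  fail_rows <- function(bad, why) {
    stop(why, " (row", if (sum(bad) > 1L) "s", " ",
         paste(utils::head(which(bad), 10L), collapse = ", "),
         if (sum(bad) > 10L) ", ..." else "", ")", call. = FALSE)
  }

  bad <- !(responses$time %in% time_points)
  if (any(bad)) fail_rows(bad, paste0("time not in {", paste(time_points, collapse = ","), "}"))
  bad <- !(responses$item_id %in% questionnaire$items$item_id)
  if (any(bad)) fail_rows(bad, "unknown item_id")
  opt_key <- paste0(responses$item_id, "\r", responses$option)
  valid_key <- unlist(lapply(names(questionnaire$options), function(id) {
    paste0(id, "\r", questionnaire$options[[id]])
  }), use.names = FALSE)
  bad <- !(opt_key %in% valid_key)
  if (any(bad)) fail_rows(bad, "option not among the item's options")
  cell <- paste0(responses$member_id, "\r", responses$team_id, "\r",
                 responses$time, "\r", responses$item_id)
  bad <- duplicated(paste0(cell, "\r", responses$option))
  if (any(bad)) fail_rows(bad, "duplicated response row")
  mode_of <- stats::setNames(questionnaire$items$response_mode, questionnaire$items$item_id)
  bad <- duplicated(cell) & mode_of[responses$item_id] == "single"
  if (any(bad)) fail_rows(bad, "multiple selections on a single-choice item")

  grp <- tapply(responses$group, responses$team_id, function(g) unique(g))
  multi_grp <- names(grp)[lengths(grp) > 1L]
  if (length(multi_grp)) {
    stop("team(s) allocated to more than one group: ", paste(multi_grp, collapse = ", "))
  }
  groups <- vapply(grp, `[[`, "", 1L)
  sizes <- vapply(split(responses$member_id, responses$team_id),
                  function(m) length(unique(m)), 0L)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    stop("team(s) with fewer than 2 responding members: ", paste(small, collapse = ", "))
  }

  structure(
    list(
      questionnaire = questionnaire,
      responses = responses,
      groups = groups,
      team_sizes = sizes,
      time_points = time_points
    ),
    class = "smm_study"
  )
}

#' @export
print.smm_study <- function(x, ...) {
  cat("Team questionnaire study\n")
  cat("  teams:", length(x$groups), "(",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)), collapse = ", "), ")\n")
  cat("  members:", sum(x$team_sizes),
      " team sizes ", paste(range(x$team_sizes), collapse = "-"), "\n", sep = "")
  cat("  items:", nrow(x$questionnaire$items),
      " time points: ", paste(x$time_points, collapse = ", "), "\n", sep = "")
  cat("  response rows:", nrow(x$responses), "\n")
  invisible(x)
}

#' Read and write long-format response files
#'
#' The on-disk format is a UTF-8 CSV (or TSV, chosen by extension) with a
#' header row and columns `group,team_id,member_id,time,item_id,option`, one
#' row per selected option. Multiple-choice selections therefore occupy one
#' row per chosen option; missing responses have no rows.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @param questionnaire A [questionnaire_spec()] used for validation.
#' @param time_points Allowed time points, passed to [smm_study()].
#' @return `read_responses()` returns a validated [smm_study()];
#'   `write_responses()` returns `path` invisibly. Reading back a written
#'   study reproduces it exactly.
#' @export
read_responses <- function(path, questionnaire, time_points = c("pre", "post")) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", fileEncoding = "UTF-8")
  smm_study(df, questionnaire, time_points = time_points)
}

#' @param study An [smm_study()].
#' @rdname read_responses
#' @export
write_responses <- function(study, path) {
  stopifnot(inherits(study, "smm_study"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(study$responses, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert wide single-choice data to the long response format
#'
#' Convenience converter for spreadsheets holding one column per item and
#' one row per member/time. Multiple-choice cells may hold several options
#' separated by `sep`.
#'
#' @param wide Data frame with columns `group`, `team_id`, `member_id`,
#'   `time`, plus one column per item id.
#' @param sep Separator splitting multiple selections within a cell.
#' @return Long-format data frame suitable for [smm_study()]. Empty cells
#'   (`""` or `NA`) become missing responses (no rows).
#' @export
wide_to_long <- function(wide, sep = ";") {
  idcols <- c("group", "team_id", "member_id", "time")
  miss <- setdiff(idcols, names(wide))
  if (length(miss)) stop("wide data missing column(s): ", paste(miss, collapse = ", "))
  items <- setdiff(names(wide), idcols)
  out <- lapply(items, function(it) {
    val <- as.character(wide[[it]])
    keep <- !is.na(val) & nzchar(val)
    if (!any(keep)) return(NULL)
    sel <- strsplit(val[keep], sep, fixed = TRUE)
    idx <- rep(which(keep), lengths(sel))
    data.frame(
      group = wide$group[idx], team_id = wide$team_id[idx],
      member_id = wide$member_id[idx], time = wide$time[idx],
      item_id = it, option = trimws(unlist(sel)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Report scorability problems without mutating the data
#'
#' Pairwise similarity for an item needs at least two responding members per
#' team and time point. This report lists every (team, time, item) cell that
#' falls short of that minimum, with the number of responders found. Cells
#' are flagged, never dropped: exclusion decisions stay with the analyst.
#'
#' @param study An [smm_study()].
#' @param min_responders Minimum members per cell for scoring (default 2).
#' @return Data frame with columns `team_id`, `time`, `item_id`,
#'   `n_responders`; zero rows when every cell is scorable. Idempotent and
#'   side-effect free.
#' @export
validate_study <- function(study, min_responders = 2L) {
  stopifnot(inherits(study, "smm_study"))
  r <- study$responses
  teams <- names(study$groups)
  items <- study$questionnaire$items$item_id
  grid <- expand.grid(
    team_id = teams, time = study$time_points, item_id = items,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  key <- paste0(r$team_id, "\r", r$time, "\r", r$item_id)
  nresp <- vapply(split(r$member_id, key), function(m) length(unique(m)), 0L)
  gkey <- paste0(grid$team_id, "\r", grid$time, "\r", grid$item_id)
  grid$n_responders <- ifelse(gkey %in% names(nresp), nresp[gkey], 0L)
  out <- grid[grid$n_responders < min_responders, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$team_id, out$time, out$item_id), , drop = FALSE]
}
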