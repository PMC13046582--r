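#' Define a questionnaire instrument
#'
#' A questionnaire is a set of nominal items, each belonging to one of two
#' content domains (task responsibility or communication) and answered either
#' in single-choice mode (pick exactly one option) or multiple-choice mode
#' (pick any non-empty subset of options). Option identifiers are opaque
#' strings with no ordering semantics; agreement scoring treats them as
#' purely nominal.
#'
#' @param item_id Character vector of unique item identifiers.
#' @param domain Character vector, one of `"task_responsibility"` or
#'   `"communication"` per item (recycled if length 1).
#' @param response_mode Character vector, `"single"` or `"multi"` per item
#'   (recycled if length 1).
#' @param options List of character vectors, the response options per item
#'   (each of length >= 2), or a single character vector shared by all items.
#' @return An object of class `questionnaire_spec`: a list with an `items`
#'   data frame (`item_id`, `domain`, `response_mode`, `n_options`) and an
#'   `options` list mapping item id to its option labels.
#' @examples
#' q <- questionnaire_spec(
#'   item_id = c("t1", "c1"),
#'   domain = c("task_responsibility", "communication"),
#'   response_mode = c("single", "multi"),
#'   options = list(c("leader", "nurse", "anesthetist"), c("a", "b", "c"))
#' )
#' q
#' @seealso [default_questionnaire()] for the bundled 54-item instrument.
#' @export
questionnaire_spec <- function(item_id, domain, response_mode, options) {
  item_id <- as.character(item_id)
  n <- length(item_id)
  if (n < 1L) stop("questionnaire needs at least one item")
  if (anyDuplicated(item_id)) {
    stop("duplicate item_id: ", paste(unique(item_id[duplicated(item_id)]), collapse = ", "))
  }
  domain <- rep_len(as.character(domain), n)
  response_mode <- rep_len(as.character(response_mode), n)
  bad_dom <- setdiff(unique(domain), c("task_responsibility", "communication"))
  if (length(bad_dom)) stop("unknown domain: ", paste(bad_dom, collapse = ", "))
  bad_mode <- setdiff(unique(response_mode), c("single", "multi"))
  if (length(bad_mode)) stop("unknown response_mode: ", paste(bad_mode, collapse = ", "))
  if (is.character(options)) options <- rep(list(options), n)
  if (length(options) != n) stop("`options` must have one entry per item")
  options <- lapply(options, as.character)
  m <- lengths(options)
  if (any(m < 2L)) stop("every item needs at least 2 options")
  if (any(vapply(options, anyDuplicated, 0L) > 0L)) {
    stop("option labels must be unique within an item")
  }
  names(options) <- item_id
  structure(
    list(
      items = data.frame(
        item_id = item_id, domain = domain,
        response_mode = response_mode, n_options = as.integer(m),
        stringsAsFactors = FALSE
      ),
      options = options
    ),
    class = "questionnaire_spec"
  )
}

#' The default 54-item team instrument
#'
#' Builds the study-shaped instrument: a task-responsibility subscale of 26
#' items (21 single-choice, 5 multiple-choice) and a communication subscale
#' of 28 multiple-choice items. The published source does not reproduce the
#' item wording or the option counts, so items carry placeholder labels
#' (`task01` ... `task26`, `comm01` ... `comm28`) and a configurable number
#' of options per item.
#'
#' @param n_options Number of response options per item; a single value or a
#'   vector recycled over the 54 items. Default 5, a typical role-roster
#'   size for a five-to-nine-person trauma team.
#' @return A [questionnaire_spec()] with 54 items.
#' @examples
#' q <- default_questionnaire()
#' table(q$items$domain, q$items$response_mode)
#' @export
default_questionnaire <- function(n_options = 5L) {
  ids <- c(sprintf("task%02d", 1:26), sprintf("comm%02d", 1:28))
  m <- rep_len(as.integer(n_options), 54L)
  questionnaire_spec(
    item_id = ids,
    domain = rep(c("task_responsibility", "communication"), c(26L, 28L)),
    response_mode = rep(c("single", "multi", "multi"), c(21L, 5L, 28L)),
    options = lapply(m, function(k) sprintf("opt%d", seq_len(k)))
  )
}

#' @export
print.questionnaire_spec <- function(x, ...) {
  it <- x$items
  cat("Questionnaire:", nrow(it), "items\n")
  tab <- table(domain = it$domain, mode = it$response_mode)
  print(tab)
  cat("options per item:", paste(range(it$n_options), collapse = "-"), "\n")
  invisible(x)
}

#' Read or write a questionnaire specification
#'
#' Questionnaire specifications are stored as JSON or YAML documents with one
#' record per item (`item_id`, `domain`, `response_mode`, `options`). The
#' format is chosen from the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return `read_questionnaire()` returns a [questionnaire_spec()];
#'   `write_questionnaire()` returns `path` invisibly.
#' @export
read_questionnaire <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  items <- doc$items
  if (is.null(items)) stop("questionnaire document must have an 'items' field")
  questionnaire_spec(
    item_id = vapply(items, function(i) i$item_id, ""),
    domain = vapply(items, function(i) i$domain, ""),
    response_mode = vapply(items, function(i) i$response_mode, ""),
    options = lapply(items, function(i) unlist(i$options))
  )
}

#' @param spec A [questionnaire_spec()].
#' @rdname read_questionnaire
#' @export
write_questionnaire <- function(spec, path) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  items <- lapply(seq_len(nrow(spec$items)), function(i) {
    list(
      item_id = spec$items$item_id[i],
      domain = spec$items$domain[i],
      response_mode = spec$items$response_mode[i],
      options = spec$options[[i]]
    )
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(list(items = items), path)
  } else {
    jsonlite::write_json(list(items = items), path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
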