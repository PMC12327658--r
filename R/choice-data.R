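#' Long-format best-worst response data
#'
#' Bundles a set of best/worst selections with the design they were collected
#' under. Each record is one answered choice set: a respondent id, a block id
#' (1-based, matching the design file numbering), and the labels picked as
#' most and least important. Validation enforces that the block exists, both
#' labels belong to that block, best differs from worst, and no
#' (respondent, block) pair occurs twice. Skipped tasks are simply absent:
#' the likelihood is a product over observed tasks only.
#'
#' @param design a [bws_design()] object.
#' @param choices data frame with columns `respondent`, `block`, `best`,
#'   `worst`.
#' @return An object of class `"bws_data"`: list with `design`, the validated
#'   `choices` data frame, `n_respondents` and `n_tasks`.
#' @examples
#' design <- cyclic_bws_design(letters[1:7], set_size = 3)
#' resp <- data.frame(respondent = "r1", block = 1,
#'                    best = design$items[design$blocks[1, 1]],
#'                    worst = design$items[design$blocks[1, 2]])
#' bws_data(design, resp)
#' @export
bws_data <- function(design, choices) {
  stopifnot(inherits(design, "bws_design"))
  need <- c("respondent", "block", "best", "worst")
  if (!all(need %in% names(choices))) {
    stop("'choices' must have columns respondent, block, best, worst")
  }
  choices <- data.frame(
    respondent = as.character(choices$respondent),
    block = as.integer(choices$block),
    best = as.character(choices$best),
    worst = as.character(choices$worst),
    stringsAsFactors = FALSE)

  .row_fail <- function(bad, msg) {
    if (any(bad)) {
      stop(sprintf("invalid choice record(s) at row %s: %s",
                   paste(which(bad), collapse = ", "), msg), call. = FALSE)
    }
  }
  .row_fail(is.na(choices$block) | choices$block < 1L | choices$block > design$b,
            "unknown block id")
  .row_fail(!(choices$best %in% design$items), "unknown 'best' item label")
  .row_fail(!(choices$worst %in% design$items), "unknown 'worst' item label")
  .row_fail(choices$best == choices$worst, "best and worst must differ")
  in_block <- function(lab) {
    idx <- match(lab, design$items)
    rowSums(design$blocks[choices$block, , drop = FALSE] == idx) > 0L
  }
  .row_fail(!in_block(choices$best), "'best' item not in the stated block")
  .row_fail(!in_block(choices$worst), "'worst' item not in the stated block")
  .row_fail(duplicated(choices[c("respondent", "block")]),
            "duplicate (respondent, block) record")

  structure(
    list(design = design,
         choices = choices,
         n_respondents = length(unique(choices$respondent)),
         n_tasks = nrow(choices)),
    class = "bws_data")
}

#' @export
print.bws_data <- function(x, ...) {
  cat(sprintf("BWS responses: %d tasks from %d respondents (%d items, %d sets of %d)\n",
              x$n_tasks, x$n_respondents, x$design$v, x$design$b, x$design$k))
  invisible(x)
}

#' Read and write response files
#'
#' Responses are stored as CSV with header `respondent,block,best,worst`, one
#' row per answered choice set. All validation of [bws_data()] applies;
#' errors name the offending data row.
#'
#' @param path file path.
#' @param design the [bws_design()] the responses refer to.
#' @param data a [bws_data()] object.
#' @return `read_choices()` returns a `"bws_data"`; `write_choices()`
#'   invisibly returns `path`.
#' @export
read_choices <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(respondent = "character"))
  bws_data(design, df)
}

#' @rdname read_choices
#' @export
write_choices <- function(data, path) {
  stopifnot(inherits(data, "bws_data"))
  utils::write.csv(data$choices, path, row.names = FALSE)
  invisible(path)
}

#' Expand responses into ordered best-worst candidate pairs
#'
#' The maximum-difference likelihood treats each answered choice set as one
#' draw from the \eqn{k (k - 1)} ordered (best, worst) pairs of distinct
#' options in that set. This helper materialises that pair space: for every
#' record it lists all candidate pairs with the selected one flagged.
#'
#' @param data a [bws_data()] object.
#' @return A data frame with one row per (record, candidate pair): columns
#'   `task` (record number), `respondent`, `block`, `best`, `worst` (the
#'   candidate pair labels) and logical `chosen`. Each task contributes
#'   exactly `k * (k - 1)` rows, exactly one of them chosen.
#' @export
expand_pairs <- function(data) {
  stopifnot(inherits(data, "bws_data"))
  design <- data$design
  k <- design$k
  npair <- k * (k - 1L)
  # per-block table of ordered index pairs, best varies slowest
  grid <- expand.grid(worst = seq_len(k), best = seq_len(k))
  grid <- grid[grid$best != grid$worst, c("best", "worst")]
  ch <- data$choices
  n <- nrow(ch)
  out <- data.frame(
    task = rep(seq_len(n), each = npair),
    respondent = rep(ch$respondent, each = npair),
    block = rep(ch$block, each = npair),
    best = character(n * npair),
    worst = character(n * npair),
    chosen = logical(n * npair),
    stringsAsFactors = FALSE)
  for (t in seq_len(n)) {
    idx <- design$blocks[ch$block[t], ]
    rows <- (t - 1L) * npair + seq_len(npair)
    out$best[rows] <- design$items[idx[grid$best]]
    out$worst[rows] <- design$items[idx[grid$worst]]
    out$chosen[rows] <- out$best[rows] == ch$best[t] & out$worst[rows] == ch$worst[t]
  }
  out
}
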