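#' Find a cyclic difference set
#'
#' Searches \eqn{Z_v} exhaustively for a \eqn{(v, k, \lambda)} difference set:
#' a \eqn{k}-subset whose \eqn{k(k-1)} ordered differences cover every nonzero
#' residue modulo \eqn{v} exactly \eqn{\lambda} times. Cyclic development of
#' such a set (see [cyclic_bws_design()]) yields a balanced incomplete block
#' design with \eqn{b = v} blocks, replication \eqn{r = k} and pair
#' co-occurrence \eqn{\lambda}.
#'
#' The search is deterministic: candidates are \eqn{k}-subsets containing 0,
#' enumerated in lexicographic order, and the first valid set is returned.
#' The necessary counting condition \eqn{\lambda (v - 1) = k (k - 1)} is
#' checked up front.
#'
#' @param v modulus (number of items), integer \eqn{\ge 3}.
#' @param k block size, integer with \eqn{2 \le k < v}.
#' @param lambda required pair co-occurrence count.
#' @return Integer vector of `k` residues in `0:(v-1)`, sorted increasing,
#'   always containing 0.
#' @examples
#' find_difference_set(7, 3, 1)    # the Fano-plane set {0, 1, 3}
#' find_difference_set(15, 7, 3)
#' @seealso [cyclic_bws_design()], [check_balance()]
#' @export
find_difference_set <- function(v, k, lambda) {
  v <- as.integer(v); k <- as.integer(k); lambda <- as.integer(lambda)
  if (v < 3L) stop("'v' must be at least 3")
  if (k < 2L || k >= v) stop("'k' must satisfy 2 <= k < v")
  if (lambda * (v - 1L) != k * (k - 1L)) {
    stop(sprintf(
      "no (%d, %d, %d) difference set exists: lambda*(v-1) = %d but k*(k-1) = %d",
      v, k, lambda, lambda * (v - 1L), k * (k - 1L)))
  }
  cand <- utils::combn(seq_len(v - 1L), k - 1L)
  for (j in seq_len(ncol(cand))) {
    D <- c(0L, cand[, j])
    if (.is_difference_set(D, v, lambda)) return(D)
  }
  stop(sprintf("exhaustive search found no (%d, %d, %d) difference set", v, k, lambda))
}

# ordered differences of D cover each nonzero residue mod v exactly lambda times
.is_difference_set <- function(D, v, lambda) {
  d <- outer(D, D, "-")
  d <- d[d != 0L] %% v
  all(tabulate(d, nbins = v - 1L) == lambda)
}

#' Construct a best-worst scaling design
#'
#' `bws_design()` creates a choice-set layout for a BWS questionnaire: `b`
#' blocks (choice sets), each an ordered subset of the item labels, with every
#' label appearing at most once per block. `cyclic_bws_design()` builds the
#' blocks by cyclic development of a difference set: block \eqn{j} contains
#' items \eqn{(d + j) \bmod v} for each residue \eqn{d} in the set, giving a
#' balanced incomplete block design in which every item appears in exactly
#' \eqn{k} blocks and every pair of items co-occurs in exactly
#' \eqn{k (k - 1) / (v - 1)} blocks.
#'
#' The common questionnaire used as the worked example throughout this
#' package — 15 items in 15 sets of 7 options, every item appearing 7 times
#' and every pair together 3 times — is `cyclic_bws_design(items)` with 15
#' labels.
#'
#' @param items character vector of unique item labels, length \eqn{\ge 3}.
#' @param blocks integer matrix, one row per choice set, entries indexing
#'   `items` (1-based); all rows the same width \eqn{k} with
#'   \eqn{3 \le k \le v} and no repeats within a row.
#' @param diff_set difference set of residues modulo `length(items)`, as
#'   returned by [find_difference_set()]; found automatically when `NULL`.
#' @param set_size number of options per choice set (`k`); defaults to the
#'   size of `diff_set`.
#' @return An object of class `"bws_design"`: a list with elements `items`,
#'   `blocks` (b x k integer matrix), and counts `v`, `b`, `k`.
#' @examples
#' design <- cyclic_bws_design(letters[1:7], set_size = 3)
#' design
#' check_balance(design)
#' @export
bws_design <- function(items, blocks) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop("item labels must be unique")
  v <- length(items)
  if (v < 3L) stop("a BWS item set needs at least 3 items")
  blocks <- as.matrix(blocks)
  storage.mode(blocks) <- "integer"
  k <- ncol(blocks)
  if (k < 3L || k > v) stop("block size must satisfy 3 <= k <= v")
  if (any(blocks < 1L) || any(blocks > v)) stop("block entries must index 'items'")
  if (any(apply(blocks, 1L, anyDuplicated) > 0L)) {
    stop("an item may appear only once within a choice set")
  }
  structure(
    list(items = items, blocks = unname(blocks),
         v = v, b = nrow(blocks), k = k),
    class = "bws_design")
}

#' @rdname bws_design
#' @export
cyclic_bws_design <- function(items, set_size = NULL, diff_set = NULL) {
  items <- as.character(items)
  v <- length(items)
  if (is.null(diff_set)) {
    if (is.null(set_size)) stop("supply either 'set_size' or 'diff_set'")
    k <- as.integer(set_size)
    lambda <- k * (k - 1L) / (v - 1L)
    if (lambda != round(lambda)) {
      stop(sprintf(
        "no balanced cyclic design: k(k-1)/(v-1) = %d*%d/%d is not an integer",
        k, k - 1L, v - 1L))
    }
    diff_set <- find_difference_set(v, k, as.integer(lambda))
  } else {
    diff_set <- as.integer(diff_set)
    if (any(diff_set < 0L) || any(diff_set >= v)) {
      stop("'diff_set' residues must lie in 0:(v-1)")
    }
    if (!is.null(set_size) && length(diff_set) != set_size) {
      stop("'set_size' disagrees with length of 'diff_set'")
    }
  }
  blocks <- t(vapply(0:(v - 1L),
                     function(j) (diff_set + j) %% v + 1L,
                     integer(length(diff_set))))
  bws_design(items, blocks)
}

#' Tally the balance of a BWS design
#'
#' Counts, by direct enumeration, how often each item appears across the
#' choice sets (replication) and how often each unordered pair of items
#' occurs together in a set (co-occurrence), and reports whether the design
#' is a balanced incomplete block design (uniform replication `r` and uniform
#' co-occurrence `lambda`). For any design the counts satisfy
#' `sum(replication) == b * k`; for a BIBD additionally `b * k == v * r` and
#' `r * (k - 1) == lambda * (v - 1)`.
#'
#' @param design a [bws_design()] object.
#' @return An object of class `"bws_balance"`: list with `v`, `b`, `k`,
#'   per-item `replication`, per-pair `pair_counts` (v x v symmetric matrix,
#'   diagonal `NA`), scalars `r` and `lambda` (`NA` when not uniform), and
#'   logical `is_bibd`.
#' @export
check_balance <- function(design) {
  stopifnot(inherits(design, "bws_design"))
  v <- design$v
  repl <- tabulate(design$blocks, nbins = v)
  names(repl) <- design$items
  pair <- matrix(0L, v, v, dimnames = list(design$items, design$items))
  for (i in seq_len(design$b)) {
    idx <- design$blocks[i, ]
    pair[idx, idx] <- pair[idx, idx] + 1L
  }
  diag(pair) <- NA_integer_
  off <- pair[upper.tri(pair)]
  uniform_r <- length(unique(repl)) == 1L
  uniform_l <- length(unique(off)) == 1L
  structure(
    list(v = v, b = design$b, k = design$k,
         replication = repl,
         pair_counts = pair,
         r = if (uniform_r) repl[[1L]] else NA_integer_,
         lambda = if (uniform_l) off[[1L]] else NA_integer_,
         is_bibd = uniform_r && uniform_l),
    class = "bws_balance")
}

#' @export
print.bws_design <- function(x, ...) {
  cat(sprintf("BWS design: %d items, %d choice sets of %d options\n",
              x$v, x$b, x$k))
  bal <- check_balance(x)
  if (bal$is_bibd) {
    cat(sprintf("Balanced: each item appears %d times, each pair co-occurs %d times\n",
                bal$r, bal$lambda))
  } else {
    cat("Not a balanced incomplete block design (see check_balance())\n")
  }
  invisible(x)
}

#' @export
print.bws_balance <- function(x, ...) {
  cat(sprintf("BWS design balance: v = %d, b = %d, k = %d\n", x$v, x$b, x$k))
  if (x$is_bibd) {
    cat(sprintf("BIBD: r = %d, lambda = %d\n", x$r, x$lambda))
  } else {
    cat("Not balanced.\n")
    cat("Replication counts:\n")
    print(x$replication)
  }
  invisible(x)
}

#' Read and write design files
#'
#' A design file is a CSV with header `block,position,item`, one row per slot
#' of each choice set; blocks are numbered from 1 and positions give the
#' within-set order. Item labels, never internal indices, are stored.
#'
#' @param design a [bws_design()] object.
#' @param path file path.
#' @param items optional character vector giving the full item universe; by
#'   default the labels found in the file, in first-appearance order.
#' @return `read_design()` returns a `"bws_design"`; `write_design()`
#'   invisibly returns `path`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "bws_design"))
  df <- data.frame(
    block = rep(seq_len(design$b), each = design$k),
    position = rep(seq_len(design$k), times = design$b),
    item = design$items[t(design$blocks)],
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, items = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "position", "item")
  if (!all(need %in% names(df))) {
    stop("design file must have columns block, position, item")
  }
  if (is.null(items)) items <- unique(df$item)
  unknown <- setdiff(df$item, items)
  if (length(unknown)) {
    stop("design file contains labels outside the item set: ",
         paste(unknown, collapse = ", "))
  }
  df <- df[order(df$block, df$position), , drop = FALSE]
  ids <- sort(unique(df$block))
  sizes <- table(df$block)
  if (length(unique(sizes)) != 1L) stop("all blocks must have the same size")
  k <- as.integer(sizes[[1L]])
  blocks <- matrix(match(df$item, items), ncol = k, byrow = TRUE)
  bws_design(items, blocks)
}
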