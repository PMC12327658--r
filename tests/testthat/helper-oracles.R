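# Independent oracles used to pin expected values. These deliberately avoid
# the package's aggregated-likelihood code path: every ordered pair of every
# record is enumerated explicitly.

# log-likelihood by brute-force pair enumeration
oracle_loglik <- function(data, utilities) {
  design <- data$design
  u <- utilities
  if (!is.null(names(u))) u <- u[design$items]
  total <- 0
  for (t in seq_len(nrow(data$choices))) {
    rec <- data$choices[t, ]
    idx <- design$blocks[rec$block, ]
    labs <- design$items[idx]
    w <- c()
    for (a in labs) for (b in labs) if (a != b) {
      w[paste(a, b, sep = "\r")] <- exp(u[[match(a, design$items)]] -
                                        u[[match(b, design$items)]])
    }
    p <- w / sum(w)
    total <- total + log(p[[paste(rec$best, rec$worst, sep = "\r")]])
  }
  total
}

# difference-multiset check: every nonzero residue mod v hit exactly lambda times
oracle_is_difference_set <- function(D, v, lambda) {
  counts <- integer(v - 1)
  for (x in D) for (y in D) if (x != y) {
    r <- (x - y) %% v
    counts[r] <- counts[r] + 1L
  }
  all(counts == lambda)
}

# small designs reused across tests
design7_3 <- function() cyclic_bws_design(letters[1:7], set_size = 3)
design7_4 <- function() cyclic_bws_design(letters[1:7], set_size = 4)
design15_7 <- function() cyclic_bws_design(self_medication_factors(), set_size = 7)
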