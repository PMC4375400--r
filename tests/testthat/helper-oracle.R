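# Independent oracles used to cross-check the implementation.
# Kept deliberately naive: exhaustive dynamic programming, path enumeration
# and residue-level interval marking, none of which share code with the
# package internals they verify.

oracle_submat <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) {
      return(cache)
    }
    env <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62
    for (aa in c("U", "O")) {
      m <- rbind(m, setNames(rep(-4L, ncol(m)), colnames(m)))
      rownames(m)[nrow(m)] <- aa
      m <- cbind(m, setNames(rep(-4L, nrow(m)), rownames(m)))
      colnames(m)[ncol(m)] <- aa
      m[aa, aa] <- 1L
    }
    cache <<- m
    cache
  }
})

# Ends-free global (dovetail) alignment with affine gaps, full DP with
# traceback. `a` is the seed (coverage is measured on it), `b` the member.
# Gap of length L costs gap_open + L * gap_ext. Leading/trailing unaligned
# stretches of either (single) sequence are free. Returns score, identity
# over the shorter sequence, and the aligned span fraction of the seed.
oracle_align <- function(a, b, gap_open = 10, gap_ext = 1) {
  sm <- oracle_submat()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap consuming `a` (vertical)
  Y <- matrix(NEG, n + 1, m + 1) # gap consuming `b` (horizontal)
  S <- sm[av, bv, drop = FALSE]
  for (i in seq_len(n)) {
    Bprev <- if (i == 1) {
      rep(0, m + 1)
    } else {
      t <- pmax(M[i, ], X[i, ], Y[i, ])
      t[1] <- 0 # free leading gap in b direction (j == 0 border)
      t
    }
    M[i + 1, 2:(m + 1)] <- S[i, ] + Bprev[1:m]
    X[i + 1, 2:(m + 1)] <- pmax(
      M[i, 2:(m + 1)] - gap_open - gap_ext,
      X[i, 2:(m + 1)] - gap_ext,
      Y[i, 2:(m + 1)] - gap_open - gap_ext
    )
    W <- pmax(M[i + 1, 2:(m + 1)], X[i + 1, 2:(m + 1)]) - gap_open +
      seq_len(m) * gap_ext
    if (m > 1) {
      Y[i + 1, 3:(m + 1)] <- cummax(W)[1:(m - 1)] - (2:m) * gap_ext
    }
  }
  # best cell on the bottom/right border (trailing gaps free)
  border <- rbind(
    cbind(n + 1, 1 + seq_len(m)),
    cbind(1 + seq_len(n), m + 1)
  )
  vals <- pmax(M[border], X[border], Y[border])
  best <- max(vals)
  cand <- border[vals == best, , drop = FALSE]
  cand <- cand[order(-cand[, 1], -cand[, 2]), , drop = FALSE]
  i <- cand[1, 1] - 1L
  j <- cand[1, 2] - 1L
  state <- if (M[i + 1, j + 1] == best) "M" else if (X[i + 1, j + 1] == best) "X" else "Y"
  matches <- 0L
  i_max <- NA_integer_
  i_min <- NA_integer_
  repeat {
    if (state == "M") {
      if (is.na(i_max)) i_max <- i
      i_min <- i
      if (av[i] == bv[j]) matches <- matches + 1L
      target <- M[i + 1, j + 1] - S[i, j]
      ii <- i - 1L
      jj <- j - 1L
      if (ii >= 1 && jj >= 1 && M[ii + 1, jj + 1] == target) {
        state <- "M"
      } else if (ii >= 1 && jj >= 1 && X[ii + 1, jj + 1] == target) {
        state <- "X"
      } else if (ii >= 1 && jj >= 1 && Y[ii + 1, jj + 1] == target) {
        state <- "Y"
      } else {
        break # free border start
      }
      i <- ii
      j <- jj
    } else if (state == "X") {
      target <- X[i + 1, j + 1]
      if (M[i, j + 1] - gap_open - gap_ext == target) {
        state <- "M"
      } else if (X[i, j + 1] - gap_ext == target) {
        state <- "X"
      } else {
        state <- "Y"
      }
      i <- i - 1L
    } else {
      target <- Y[i + 1, j + 1]
      if (M[i + 1, j] - gap_open - gap_ext == target) {
        state <- "M"
      } else if (Y[i + 1, j] - gap_ext == target) {
        state <- "Y"
      } else {
        state <- "X"
      }
      j <- j - 1L
    }
  }
  list(
    score = best,
    matches = matches,
    identity_fraction = matches / min(n, m),
    seed_coverage = (i_max - i_min + 1L) / n
  )
}

# Transitive closure by exhaustive path enumeration with deduplication.
oracle_closure <- function(edges, term, direction) {
  step <- if (direction == "ancestors") {
    function(t) edges$parent[edges$child == t]
  } else {
    function(t) edges$child[edges$parent == t]
  }
  seen <- character(0)
  walk <- function(t) {
    for (nxt in step(t)) {
      seen <<- c(seen, nxt) # multiplicity on purpose; dedup at the end
      walk(nxt)
    }
  }
  walk(term)
  sort(unique(seen))
}

# ROC50 staircase computed literally from the curve definition.
oracle_roc50 <- function(labels, n_true, max_fp = 50L) {
  area <- 0
  tp <- 0L
  fp <- 0L
  for (lab in labels) {
    if (lab) {
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
      area <- area + tp
      if (fp == max_fp) break
    }
  }
  n_fp_used <- min(max_fp, fp)
  if (n_fp_used == 0L) {
    return(tp / n_true)
  }
  area / (n_fp_used * n_true)
}

# Interval union coverage by marking residues one by one.
oracle_interval_union <- function(starts, ends, len) {
  covered <- logical(len)
  for (k in seq_along(starts)) covered[starts[k]:ends[k]] <- TRUE
  sum(covered) / len
}

# Random sequences for fixtures.
random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Substitute exactly k positions of a sequence (always to a different residue).
substitute_k <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], chars[p]), 1)
  }
  paste(chars, collapse = "")
}
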