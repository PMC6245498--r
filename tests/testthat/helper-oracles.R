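# Independent oracles and fixture builders used across the suite.

# Random small categorical table: M rows, n_attr attributes, each with its
# own small alphabet.  Returns an apc_table without class labels.
random_apc <- function(m, n_attr, alphabet_sizes = NULL) {
  if (is.null(alphabet_sizes)) {
    alphabet_sizes <- sample(2:4, n_attr, replace = TRUE)
  }
  cols <- lapply(alphabet_sizes, function(k) {
    sample(letters[seq_len(k)], m, replace = TRUE)
  })
  values <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  names(values) <- paste0("S", seq_len(n_attr))
  apc_table(values, sequence_ids = paste0("seq", seq_len(m)))
}

# Brute-force residual oracle for one attribute pair: builds the 2-way
# contingency table from scratch and applies the textbook formulas via
# chisq.test ($residuals = Pearson/standardized, $stdres = Haberman
# adjusted).  Attributes with a single observed level have all residuals 0
# (standardized) / 0 by convention (adjusted denominator vanishes).
oracle_pair_residuals <- function(x, y, mode) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    res <- tab * 0
    return(res)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (mode == "standardized") ct$residuals else ct$stdres
}

# Full-matrix oracle: assembles the I x I residual matrix event pair by
# event pair through oracle_pair_residuals.
oracle_srv <- function(apc, mode) {
  schema <- event_schema(apc)
  ev <- schema$events
  I <- schema$I
  out <- matrix(0, I, I, dimnames = list(ev$key, ev$key))
  cols <- lapply(apc$values, as.character)
  if (!is.na(schema$class_attribute)) {
    cols[[schema$class_attribute]] <- apc$class_labels
  }
  n_attr <- length(cols)
  for (a in seq_len(n_attr - 1L)) {
    for (b in seq((a + 1L), n_attr)) {
      r <- oracle_pair_residuals(cols[[a]], cols[[b]], mode)
      for (vi in rownames(r)) {
        for (vj in colnames(r)) {
          ki <- paste0(schema$attributes[a], "=", vi)
          kj <- paste0(schema$attributes[b], "=", vj)
          val <- r[vi, vj]
          if (!is.finite(val)) val <- 0
          out[ki, kj] <- val
          out[kj, ki] <- val
        }
      }
    }
  }
  out
}

# Brute-force dominant-eigenpair oracle for symmetric PSD matrices via
# power iteration with deflation; used against pcd() on tiny matrices.
oracle_eigen <- function(mat, tol = 1e-12, max_iter = 100000L) {
  stopifnot(isSymmetric(mat))
  n <- nrow(mat)
  vals <- numeric(n)
  vecs <- matrix(0, n, n)
  A <- mat
  for (k in seq_len(n)) {
    v <- rep(1 / sqrt(n), n)
    lambda <- 0
    for (it in seq_len(max_iter)) {
      w <- A %*% v
      nw <- sqrt(sum(w^2))
      if (nw < tol) { lambda <- 0; break }
      v_new <- drop(w / nw)
      if (sum((v_new - v)^2) < tol^2 || sum((v_new + v)^2) < tol^2) {
        v <- v_new
        lambda <- drop(t(v) %*% mat %*% v)
        break
      }
      v <- v_new
      lambda <- nw
    }
    if (lambda < tol) break
    lambda <- drop(t(v) %*% A %*% v)
    vals[k] <- lambda
    vecs[, k] <- v
    A <- A - lambda * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}

# Tiny fixed residue APC shared by several io tests.
toy_apc <- function() {
  apc_table(data.frame(S1 = c("a", "a", "b", "b"),
                       S2 = c("x", "x", "y", "y"),
                       stringsAsFactors = FALSE),
            sequence_ids = c("s1", "s2", "s3", "s4"))
}
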