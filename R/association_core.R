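#' Enumerate the event schema of a categorical APC
#'
#' Lists, per attribute, the distinct event values observed, in a
#' deterministic (radix-sorted) order so that the schema — and everything
#' keyed by it — is invariant to row permutations of the table.  When class
#' labels are present and `include_class = TRUE`, the class is appended as
#' one extra categorical attribute so class-residue associations appear in
#' the frequency matrix alongside residue-residue ones.
#'
#' @param apc fully categorical [apc_table()].
#' @param include_class include class labels as an attribute when present.
#' @param class_attribute label used for the class attribute.
#' @return An object of class `event_schema`: list with `events` (a
#'   data.frame of `attribute`, `value`, `key`, and the attribute index
#'   `attr_index`), `attributes` (attribute labels in order),
#'   `class_attribute` (label or `NA`), and `I` (total event count).
#' @export
event_schema <- function(apc, include_class = TRUE,
                         class_attribute = "Class") {
  stopifnot(inherits(apc, "apc_table"))
  if (any(apc$attribute_kinds != "categorical")) {
    stop("event_schema requires a fully categorical APC; run maybe_discretize first")
  }
  attrs <- apc$site_labels
  cols <- lapply(apc$values, as.character)
  has_class <- include_class && !is.null(apc$class_labels)
  if (has_class) {
    if (class_attribute %in% attrs) {
      stop("class attribute label collides with a site label: ",
           class_attribute)
    }
    attrs <- c(attrs, class_attribute)
    cols <- c(cols, list(apc$class_labels))
  }
  ev <- do.call(rbind, lapply(seq_along(attrs), function(n) {
    vals <- sort(unique(cols[[n]][!is.na(cols[[n]])]), method = "radix")
    data.frame(attribute = attrs[n], value = vals,
               key = paste0(attrs[n], "=", vals),
               attr_index = n, stringsAsFactors = FALSE)
  }))
  rownames(ev) <- NULL
  structure(list(events = ev, attributes = attrs,
                 class_attribute = if (has_class) class_attribute else NA_character_,
                 I = nrow(ev)),
            class = "event_schema")
}

#' @export
print.event_schema <- function(x, ...) {
  cat(sprintf("event_schema: %d attributes, I = %d events%s\n",
              length(x$attributes), x$I,
              if (is.na(x$class_attribute)) "" else
                sprintf(" (class attribute '%s')", x$class_attribute)))
  invisible(x)
}

# Internal: the categorical data columns in schema attribute order,
# including the class column when the schema carries one.
schema_columns <- function(apc, schema) {
  cols <- lapply(apc$values, as.character)
  names(cols) <- apc$site_labels
  if (!is.na(schema$class_attribute)) {
    cols[[schema$class_attribute]] <- apc$class_labels
  }
  cols[schema$attributes]
}

#' Build the I x I association frequency matrix
#'
#' Counts, for every pair of events belonging to different attributes, the
#' number of rows where both occur: the ARA (or ARPA) frequency matrix.
#' Rows with a missing cell in either attribute are excluded from that
#' attribute pair's counts (so each pair is a complete-case contingency
#' table).  Within-attribute blocks are structurally zero.
#'
#' @param apc fully categorical [apc_table()].
#' @param schema an [event_schema()] for `apc` (built with the same class
#'   handling); defaults to `event_schema(apc)`.
#' @return An object of class `ara_fm`: list with `counts` (symmetric
#'   I x I integer matrix, dimnames = event keys), `schema`, and `M` (row
#'   count of the table).
#' @export
build_frequency_matrix <- function(apc, schema = event_schema(apc)) {
  stopifnot(inherits(apc, "apc_table"), inherits(schema, "event_schema"))
  cols <- schema_columns(apc, schema)
  ev <- schema$events
  # consistency: every observed value must be in the schema
  for (n in seq_along(cols)) {
    vals <- unique(cols[[n]][!is.na(cols[[n]])])
    known <- ev$value[ev$attr_index == n]
    bad <- setdiff(vals, known)
    if (length(bad)) {
      stop(sprintf("event '%s=%s' in table but absent from schema",
                   schema$attributes[n], bad[1]))
    }
  }
  I <- schema$I
  counts <- matrix(0L, I, I, dimnames = list(ev$key, ev$key))
  idx <- split(seq_len(I), ev$attr_index)
  N <- length(cols)
  for (n in seq_len(N - 1L)) {
    fn <- factor(cols[[n]], levels = ev$value[ev$attr_index == n])
    for (n2 in seq((n + 1L), N)) {
      fn2 <- factor(cols[[n2]], levels = ev$value[ev$attr_index == n2])
      tab <- table(fn, fn2, useNA = "no")
      counts[idx[[n]], idx[[n2]]] <- tab
      counts[idx[[n2]], idx[[n]]] <- t(tab)
    }
  }
  structure(list(counts = counts, schema = schema,
                 M = length(cols[[1L]])),
            class = "ara_fm")
}

# Internal: iterate over attribute-pair blocks of an I x I matrix.
# f(ri, ci, block) is called with the row/col index vectors and the block.
map_blocks <- function(mat, schema, f) {
  idx <- split(seq_len(schema$I), schema$events$attr_index)
  N <- length(idx)
  for (n in seq_len(N - 1L)) {
    for (n2 in seq((n + 1L), N)) {
      f(idx[[n]], idx[[n2]], mat[idx[[n]], idx[[n2]], drop = FALSE])
    }
  }
  invisible(NULL)
}

#' Expected co-occurrence counts under independence
#'
#' For events of different attributes, `e_ij = occ_i * occ_j / M` with the
#' margins and M taken from that attribute pair's complete-case
#' contingency block (the block's row/column sums and total), which equals
#' the usual product-of-margins expectation when no cells are missing.
#' Within-attribute entries are 0.
#'
#' @param fm an `ara_fm` from [build_frequency_matrix()].
#' @return numeric I x I matrix of expected counts.
#' @export
expected_counts <- function(fm) {
  stopifnot(inherits(fm, "ara_fm"))
  if (fm$M == 0L) stop("empty table: M = 0")
  I <- fm$schema$I
  e <- matrix(0, I, I, dimnames = dimnames(fm$counts))
  map_blocks(fm$counts, fm$schema, function(ri, ci, block) {
    mp <- sum(block)
    if (mp > 0) {
      eb <- outer(rowSums(block), colSums(block)) / mp
      e[ri, ci] <<- eb
      e[ci, ri] <<- t(eb)
    }
  })
  e
}

#' Convert the frequency matrix into the statistical-residual vector space
#'
#' Each co-occurrence count is replaced by its statistical residual.  In
#' `standardized` mode `SR_ij = (o_ij - e_ij) / sqrt(e_ij)` (the Pearson
#' residual).  In `adjusted` mode (the default) the standardized residual
#' is further divided by `sqrt((1 - occ_i/M)(1 - occ_j/M))` — the Haberman
#' adjustment — so that under independence each entry is approximately
#' standard normal.  Margins and M are per attribute pair (complete
#' cases).  Entries with `e_ij = 0`, or a zero adjustment denominator, are
#' set to 0, as are all within-attribute entries.
#'
#' The resulting I x I matrix is viewed as a vector space (the SRV): each
#' row is the a-vector of one event, whose coordinates are its residuals
#' against every event of the other attributes.
#'
#' @param fm an `ara_fm`.
#' @param mode `"adjusted"` or `"standardized"`.
#' @param threshold significance threshold stored with the matrix
#'   (default 1.96, the two-sided 95% normal quantile).
#' @return An object of class `srv_matrix`: list with `sr` (I x I numeric
#'   matrix), `mode`, `threshold`, `schema`, `M`.
#' @export
compute_srv <- function(fm, mode = c("adjusted", "standardized"),
                        threshold = 1.96) {
  stopifnot(inherits(fm, "ara_fm"))
  mode <- match.arg(mode)
  I <- fm$schema$I
  sr <- matrix(0, I, I, dimnames = dimnames(fm$counts))
  map_blocks(fm$counts, fm$schema, function(ri, ci, block) {
    mp <- sum(block)
    if (mp == 0) return(invisible(NULL))
    rs <- rowSums(block)
    cs <- colSums(block)
    e <- outer(rs, cs) / mp
    s <- matrix(0, nrow(block), ncol(block))
    pos <- e > 0
    s[pos] <- (block[pos] - e[pos]) / sqrt(e[pos])
    if (mode == "adjusted") {
      adj <- sqrt(outer(1 - rs / mp, 1 - cs / mp))
      ok <- pos & adj > 0
      s[ok] <- s[ok] / adj[ok]
      s[pos & adj <= 0] <- 0
    }
    sr[ri, ci] <<- s
    sr[ci, ri] <<- t(s)
  })
  structure(list(sr = sr, mode = mode, threshold = threshold,
                 schema = fm$schema, M = fm$M),
            class = "srv_matrix")
}

#' @export
print.srv_matrix <- function(x, ...) {
  nsig <- sum(abs(x$sr) > x$threshold) / 2
  cat(sprintf("srv_matrix: I = %d, mode = %s, %d association(s) with |SR| > %g\n",
              x$schema$I, x$mode, nsig, x$threshold))
  invisible(x)
}

#' Classify a residual against the significance threshold
#'
#' At the 95% confidence level an association is positive significant when
#' its residual exceeds 1.96, negative significant below -1.96, and
#' irrelevant (consistent with random co-occurrence) in between.  The
#' inequalities are strict: a residual of exactly the threshold is
#' irrelevant.
#'
#' @param sr numeric vector of residuals.
#' @param threshold positive significance threshold (default 1.96).
#' @return character vector in `{"positive_significant",
#'   "negative_significant", "irrelevant"}`.
#' @export
classify_significance <- function(sr, threshold = 1.96) {
  if (threshold <= 0) stop("threshold must be positive")
  ifelse(sr > threshold, "positive_significant",
         ifelse(sr < -threshold, "negative_significant", "irrelevant"))
}

#' Export a frequency or residual matrix as CSV
#'
#' Writes the I x I matrix with a two-level header: the first row holds the
#' attribute of each column event, the second its event value.
#'
#' @param x an `ara_fm` or `srv_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  mat <- if (inherits(x, "ara_fm")) x$counts else
    if (inherits(x, "srv_matrix")) x$sr else
      stop("x must be an ara_fm or srv_matrix")
  schema <- x$schema
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("attribute", schema$events$attribute), collapse = ","), con)
  writeLines(paste(c("value", schema$events$value), collapse = ","), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(schema$events$key[i],
                       format(mat[i, ], trim = TRUE, digits = 10)),
                     collapse = ","), con)
  }
  invisible(path)
}
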