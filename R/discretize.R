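#' Discretize one numeric attribute into interval events
#'
#' Converts the numeric values of one attribute into interval event values.
#' `equal_width` splits the observed range into equal-length intervals.
#' `equal_frequency` places cut points at empirical quantiles so bin
#' occupancies are as equal as possible; `max_entropy` is the
#' equal-probability partition that maximizes the entropy of bin
#' occupancies, which is the same quantile partition (identical to
#' `equal_frequency` on tie-free data), and is provided under its own name.
#'
#' Ties never split: cut points are placed between distinct values, and
#' when a quantile falls inside a run of tied values the whole run goes to
#' the lower bin.  Requesting more bins than there are distinct values
#' reduces the bin count to the number of distinct values with a warning.
#'
#' @param values numeric vector (non-empty; NAs ignored).
#' @param method `"equal_width"`, `"equal_frequency"`, or `"max_entropy"`.
#' @param bins requested number of bins (>= 2).
#' @param attribute attribute label recorded in the scheme.
#' @return An object of class `interval_scheme`: list with `attribute`,
#'   `method`, `cuts` (strictly increasing boundaries, length bins + 1,
#'   covering the observed range), `labels` (rendered `"[lo,hi)"`, last bin
#'   closed), and `bins`.
#' @export
discretize_attribute <- function(values,
                                 method = c("equal_frequency", "equal_width",
                                            "max_entropy"),
                                 bins = 3L, attribute = "x") {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to discretize")
  if (bins < 2L) stop("bins must be >= 2")
  distinct <- sort(unique(values))
  if (bins > length(distinct)) {
    warning(sprintf(
      "attribute '%s': %d bins requested but only %d distinct values; reducing",
      attribute, bins, length(distinct)))
    bins <- length(distinct)
  }
  lo <- distinct[1]
  hi <- distinct[length(distinct)]
  if (method == "equal_width") {
    cuts <- seq(lo, hi, length.out = bins + 1L)
  } else {
    # quantile cuts; a cut lands between two distinct values so a run of
    # ties is never split (the run containing the quantile stays low)
    m <- length(values)
    cum <- cumsum(tabulate(match(values, distinct)))
    inner <- numeric(0)
    for (k in seq_len(bins - 1L)) {
      target <- k * m / bins
      t <- which(cum >= target)[1]
      if (t < length(distinct)) {
        inner <- c(inner, (distinct[t] + distinct[t + 1L]) / 2)
      }
    }
    inner <- unique(inner)
    cuts <- c(lo, inner, hi)
    bins <- length(cuts) - 1L
    if (bins < 2L) {
      stop(sprintf("attribute '%s': tie structure leaves a single bin",
                   attribute))
    }
  }
  labels <- vapply(seq_len(bins), function(b) {
    sprintf("[%s,%s%s", fmt_num(cuts[b]), fmt_num(cuts[b + 1L]),
            if (b == bins) "]" else ")")
  }, character(1))
  structure(list(attribute = attribute, method = method, cuts = cuts,
                 labels = labels, bins = bins),
            class = "interval_scheme")
}

fmt_num <- function(x) sprintf("%.8g", x)

#' Apply an interval scheme to numeric values
#'
#' Deterministic and total on the training range: every value maps to
#' exactly one bin; identical values always land in the same bin.  Values
#' outside the training range are clamped into the first/last bin.
#'
#' @param scheme an `interval_scheme`.
#' @param values numeric vector.
#' @return character vector of bin labels (NA preserved).
#' @export
apply_scheme <- function(scheme, values) {
  stopifnot(inherits(scheme, "interval_scheme"))
  idx <- findInterval(values, scheme$cuts, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- scheme$labels[idx]
  out[is.na(values)] <- NA_character_
  out
}

#' Convert a mixed-mode APC into a fully categorical one
#'
#' Numeric attributes with at least three distinct observed values are
#' replaced by interval event values via [discretize_attribute()]; numeric
#' attributes with fewer than three distinct values, and all categorical
#' attributes, pass through unchanged (the few-valued numerics as
#' categorical symbols).
#'
#' @param apc an [apc_table()], possibly mixed-mode.
#' @param method discretization method (see [discretize_attribute()]).
#' @param bins bin count per discretized attribute.
#' @return list with `apc` (fully categorical [apc_table()]) and `schemes`
#'   (list of `interval_scheme`, one per discretized attribute).
#' @export
maybe_discretize <- function(apc, method = "equal_frequency", bins = 3L) {
  stopifnot(inherits(apc, "apc_table"))
  schemes <- list()
  values <- apc$values
  kinds <- apc$attribute_kinds
  for (j in seq_along(values)) {
    if (kinds[j] != "numeric") next
    v <- values[[j]]
    ndistinct <- length(unique(v[!is.na(v)]))
    if (ndistinct < 3L) {
      values[[j]] <- ifelse(is.na(v), NA_character_, fmt_num(v))
      kinds[j] <- "categorical"
      next
    }
    sc <- discretize_attribute(v, method = method,
                               bins = min(bins, ndistinct),
                               attribute = apc$site_labels[j])
    values[[j]] <- apply_scheme(sc, v)
    kinds[j] <- "categorical"
    schemes[[apc$site_labels[j]]] <- sc
  }
  out <- apc_table(values, sequence_ids = apc$sequence_ids,
                   site_labels = apc$site_labels,
                   class_labels = apc$class_labels,
                   attribute_kinds = kinds, attr_meta = apc$attr_meta)
  list(apc = out, schemes = schemes)
}

#' Serialize interval schemes to JSON
#'
#' Written alongside results so discretization runs are auditable and
#' replayable.
#'
#' @param schemes list of `interval_scheme`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_schemes <- function(schemes, path) {
  out <- lapply(schemes, function(s) {
    list(attribute = s$attribute, method = s$method,
         cuts = s$cuts, labels = s$labels, bins = s$bins)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
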