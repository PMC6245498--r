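#' Generate the three-class entangled-pattern synthetic APC
#'
#' Emits a table of `3 * rows_per_class` rows (default 300) with a class
#' label column and five categorical attributes carrying entangled
#' class patterns:
#'
#' * class C1: `A1 = A`, `A2 = C`, `A3 = E`; `A4` uniform over `{H, G}`;
#'   `A5` uniform over `{M, N}`
#' * class C2: `A1 = A`, `A2 = D`, `A3 = F`; `A4` uniform over `{H, G}`;
#'   `A5` uniform over `{M, N}`
#' * class C3: `A1 = B`, `A2 = D`, `A3 = E`; `A4 = H`;
#'   `A5` uniform over `{M, N}`
#'
#' The design entangles the deterministic patterns across class pairs:
#' `A1=A` is shared by C1 and C2, `A2=D` by C2 and C3, and `A3=E` by C1
#' and C3, so no single attribute separates all three classes — the
#' situation per-component re-projection is meant to disentangle.
#'
#' The Mersenne-Twister generator is seeded with `seed` (recorded in the
#' ground truth), so the output is fully reproducible.
#'
#' @param seed integer RNG seed.
#' @param rows_per_class rows per class (default 100).
#' @return list with `apc` (an [apc_table()] with class labels) and
#'   `truth`: list with `class_associations` (data.frame `attribute`,
#'   `value`, `class` of the deterministic embedded associations),
#'   `entanglements` (which events are shared across which class pairs),
#'   `seed`, and `rng` (generator name).
#' @export
generate_table2 <- function(seed, rows_per_class = 100L) {
  if (rows_per_class < 1L) stop("rows_per_class must be >= 1")
  spec <- synthetic_spec(
    rows_per_class = rep(rows_per_class, 3L),
    class_names = c("C1", "C2", "C3"),
    attributes = paste0("A", 1:5),
    background = rep(list(LETTERS[1:8]), 5L),
    patterns = list(
      C1 = list(A1 = "A", A2 = "C", A3 = "E", A4 = c("H", "G"),
                A5 = c("M", "N")),
      C2 = list(A1 = "A", A2 = "D", A3 = "F", A4 = c("H", "G"),
                A5 = c("M", "N")),
      C3 = list(A1 = "B", A2 = "D", A3 = "E", A4 = "H",
                A5 = c("M", "N"))),
    embed_prob = 1.0, seed = seed)
  out <- generate_generic(spec)
  det <- out$truth$class_associations
  # A4 = H for C3 is fixed too, but A4/A5 belong to the random-pattern
  # block of the design; the announced class associations are on A1-A3
  out$truth$class_associations <-
    det[det$deterministic & det$attribute %in% c("A1", "A2", "A3"),
        c("attribute", "value", "class")]
  rownames(out$truth$class_associations) <- NULL
  out$truth$entanglements <- list(
    `C1+C2` = c("A1=A", "A4=H", "A5=M", "A5=N"),
    `C1+C3` = c("A3=E", "A4=H", "A5=M", "A5=N"),
    `C2+C3` = c("A2=D", "A4=H", "A5=M", "A5=N"))
  out
}

#' Specify a generic synthetic APC
#'
#' Describes a seeded generator for class-structured categorical or
#' mixed-mode tables: per class, per patterned attribute, either a fixed
#' value, a choice set drawn uniformly, or (for numeric attributes) a
#' sub-interval; all other cells come from the attribute's background —
#' a uniform draw over an alphabet (categorical) or over an interval
#' (numeric).
#'
#' @param rows_per_class integer vector, one entry per class.
#' @param class_names character vector of class labels.
#' @param attributes character vector of attribute labels.
#' @param background list, one element per attribute: a character alphabet
#'   or a numeric `c(lo, hi)` interval.
#' @param patterns named list (by class) of named lists (by attribute):
#'   each entry a character value/choice-set or numeric sub-interval
#'   `c(lo, hi)`.
#' @param embed_prob probability in (0, 1] that a patterned cell actually
#'   receives its pattern value (otherwise background).
#' @param seed integer RNG seed; fully determines the output.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(rows_per_class, class_names, attributes,
                           background, patterns = list(),
                           embed_prob = 1.0, seed = 1L) {
  problems <- character(0)
  if (length(rows_per_class) != length(class_names)) {
    problems <- c(problems, "rows_per_class and class_names lengths differ")
  }
  if (any(rows_per_class < 1L)) {
    problems <- c(problems, "rows_per_class entries must be >= 1")
  }
  if (length(background) != length(attributes)) {
    problems <- c(problems, "background must have one entry per attribute")
  }
  if (!(embed_prob > 0 && embed_prob <= 1)) {
    problems <- c(problems, "embed_prob must be in (0, 1]")
  }
  bad_class <- setdiff(names(patterns), class_names)
  if (length(bad_class)) {
    problems <- c(problems,
                  paste0("patterns reference unknown classes: ",
                         paste(bad_class, collapse = ", ")))
  }
  for (cl in names(patterns)) {
    bad_attr <- setdiff(names(patterns[[cl]]), attributes)
    if (length(bad_attr)) {
      problems <- c(problems,
                    paste0("patterns for class ", cl,
                           " reference unknown attributes: ",
                           paste(bad_attr, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid synthetic_spec:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(rows_per_class = as.integer(rows_per_class),
                 class_names = class_names, attributes = attributes,
                 background = background, patterns = patterns,
                 embed_prob = embed_prob, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic APC from a specification
#'
#' @param spec a [synthetic_spec()].
#' @return list with `apc` (an [apc_table()] with class labels) and
#'   `truth` (ground-truth list: `class_associations` data.frame with
#'   columns `attribute`, `value`, `class`, `deterministic`; `embed_prob`;
#'   `seed`; `rng`), sufficient to score recovery on its own.
#' @export
generate_generic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")
  m <- sum(spec$rows_per_class)
  classes <- rep(spec$class_names, spec$rows_per_class)
  numeric_attr <- vapply(spec$background, is.numeric, logical(1))
  cols <- vector("list", length(spec$attributes))
  truth_rows <- list()
  for (j in seq_along(spec$attributes)) {
    bg <- spec$background[[j]]
    col <- if (numeric_attr[j]) {
      stats::runif(m, bg[1], bg[2])
    } else {
      sample(bg, m, replace = TRUE)
    }
    for (cl in names(spec$patterns)) {
      pat <- spec$patterns[[cl]][[spec$attributes[j]]]
      if (is.null(pat)) next
      rows <- which(classes == cl)
      hit <- rows[stats::runif(length(rows)) <= spec$embed_prob]
      if (is.numeric(pat)) {
        col[hit] <- stats::runif(length(hit), pat[1], pat[2])
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(attribute = spec$attributes[j],
                     value = sprintf("[%g,%g]", pat[1], pat[2]),
                     class = cl,
                     deterministic = FALSE,
                     stringsAsFactors = FALSE)
      } else {
        col[hit] <- sample(pat, length(hit), replace = TRUE)
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(attribute = spec$attributes[j], value = pat,
                     class = cl,
                     deterministic = length(pat) == 1L &&
                       spec$embed_prob == 1,
                     stringsAsFactors = FALSE)
      }
    }
    cols[[j]] <- col
  }
  values <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  names(values) <- spec$attributes
  apc <- apc_table(values,
                   sequence_ids = sprintf("s%03d", seq_len(m)),
                   site_labels = spec$attributes,
                   class_labels = classes)
  truth <- list(class_associations = if (length(truth_rows))
    do.call(rbind, truth_rows) else
      data.frame(attribute = character(0), value = character(0),
                 class = character(0), deterministic = logical(0)),
    embed_prob = spec$embed_prob, seed = spec$seed,
    rng = "Mersenne-Twister")
  list(apc = apc, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes the table as TSV (via [write_apc()]) and the ground truth as
#' JSON next to it.
#'
#' @param synth list from [generate_table2()] or [generate_generic()].
#' @param path output TSV path; truth goes to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(synth, path) {
  write_apc(synth$apc, path)
  jsonlite::write_json(synth$truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
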