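#' Construct an aligned pattern cluster (APC) table
#'
#' An APC holds a set of aligned sequence segments from a conserved region
#' of a protein family: one row per sequence, one column per aligned site
#' (or, after property expansion, per site-property).  Cells are amino-acid
#' symbols, property categories, or numbers; an optional vector of class
#' labels (e.g. taxonomic groups) accompanies the rows.
#'
#' @param values data.frame with M rows and N >= 2 columns.  Columns may be
#'   character (categorical) or numeric.
#' @param sequence_ids character vector of M unique sequence identifiers.
#' @param site_labels character vector of N unique attribute labels.  Site
#'   labels are kept verbatim (alignment positions such as "71", "92" are
#'   common); no re-indexing is performed.
#' @param class_labels optional character vector of M class labels.
#' @param attribute_kinds optional character vector, one of `"categorical"`
#'   or `"numeric"` per column; inferred from column types when `NULL`.
#' @param attr_meta optional data.frame with columns `site` and
#'   `property_index` keying each attribute structurally (used by
#'   [expand_to_appc()]); `NULL` for plain residue APCs.
#' @return An object of class `apc_table`.
#' @seealso [read_apc()], [expand_to_appc()], [build_address_table()]
#' @export
apc_table <- function(values, sequence_ids, site_labels = colnames(values),
                      class_labels = NULL, attribute_kinds = NULL,
                      attr_meta = NULL) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  m <- nrow(values)
  n <- ncol(values)
  if (m < 1L) stop("APC must have at least one row (sequence)")
  if (n < 2L) stop("APC must have at least two attribute columns")
  sequence_ids <- as.character(sequence_ids)
  if (length(sequence_ids) != m) stop("sequence_ids must have one entry per row")
  if (anyDuplicated(sequence_ids)) {
    stop("duplicate sequence IDs: ",
         paste(unique(sequence_ids[duplicated(sequence_ids)]), collapse = ", "))
  }
  site_labels <- as.character(site_labels)
  if (length(site_labels) != n) stop("site_labels must have one entry per column")
  if (anyDuplicated(site_labels)) stop("site_labels must be unique")
  if (!is.null(class_labels)) {
    class_labels <- as.character(class_labels)
    if (length(class_labels) != m) {
      stop("class_labels must have one entry per row")
    }
  }
  if (is.null(attribute_kinds)) {
    attribute_kinds <- ifelse(vapply(values, is.numeric, logical(1)),
                              "numeric", "categorical")
  }
  attribute_kinds <- match.arg(attribute_kinds, c("categorical", "numeric"),
                               several.ok = TRUE)
  if (length(attribute_kinds) == 1L) attribute_kinds <- rep(attribute_kinds, n)
  if (length(attribute_kinds) != n) {
    stop("attribute_kinds must have one entry per column")
  }
  for (j in seq_len(n)) {
    if (attribute_kinds[j] == "categorical" && is.numeric(values[[j]])) {
      values[[j]] <- as.character(values[[j]])
    }
  }
  names(values) <- site_labels
  rownames(values) <- NULL
  structure(list(values = values,
                 sequence_ids = sequence_ids,
                 site_labels = site_labels,
                 class_labels = class_labels,
                 attribute_kinds = attribute_kinds,
                 attr_meta = attr_meta),
            class = "apc_table")
}

#' @export
print.apc_table <- function(x, ...) {
  cat(sprintf("apc_table: %d sequences x %d attributes%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$class_labels)) "" else
                sprintf(" (+ class labels, %d classes)",
                        length(unique(x$class_labels)))))
  cat("  attributes:", paste(utils::head(x$site_labels, 10), collapse = " "),
      if (length(x$site_labels) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.apc_table <- function(x) dim(x$values)

#' Read an APC table from disk
#'
#' Reads a tabular APC (TSV/CSV: first column is the sequence ID, header row
#' mandatory, remaining columns are aligned sites) or an aligned FASTA file
#' (equal-length records, one column per alignment position).  A class label
#' per sequence can be taken from a named column (tabular input) or from a
#' two-column `id<TAB>class` map file (either format).
#'
#' @param path input file path.
#' @param format one of `"tsv"`, `"csv"`, `"aligned-fasta"`.
#' @param class_source for tabular input, the name of the class column; for
#'   any format, the path to a two-column TSV class map.  `NULL` for no
#'   class labels.
#' @return An [apc_table()].
#' @export
read_apc <- function(path, format = c("tsv", "csv", "aligned-fasta"),
                     class_source = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "aligned-fasta") {
    return(read_apc_fasta(path, class_source))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", fill = FALSE)
  if (ncol(df) < 3L) stop("format error: expected id column plus >= 2 sites")
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  class_labels <- NULL
  if (!is.null(class_source)) {
    if (class_source %in% names(body)) {
      class_labels <- body[[class_source]]
      body <- body[, setdiff(names(body), class_source), drop = FALSE]
    } else if (file.exists(class_source)) {
      class_labels <- read_class_map(class_source, ids)
    } else {
      stop("unknown class column or map file: ", class_source)
    }
  }
  # numeric columns (e.g. serialized property values) are restored as numeric
  for (j in seq_along(body)) {
    v <- body[[j]]
    suppressWarnings(num <- as.numeric(v))
    if (!anyNA(num[!is.na(v) & v != ""])) body[[j]] <- num
  }
  apc_table(body, sequence_ids = ids, site_labels = names(body),
            class_labels = class_labels)
}

read_apc_fasta <- function(path, class_source) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading aligned FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readAAStringSet(path)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L) {
    stop("format error: aligned FASTA records must have equal length")
  }
  ids <- names(seqs)
  ids <- sub("\\s.*$", "", ids)  # keep accession up to first whitespace
  mat <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- as.character(seq_len(ncol(df)))
  class_labels <- if (is.null(class_source)) NULL else
    read_class_map(class_source, ids)
  apc_table(df, sequence_ids = ids, site_labels = names(df),
            class_labels = class_labels)
}

read_class_map <- function(path, ids) {
  if (!file.exists(path)) stop("class map file not found: ", path)
  cm <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(cm) < 2L) stop("class map must have two columns: id, class")
  lut <- stats::setNames(cm[[2L]], cm[[1L]])
  missing <- setdiff(ids, names(lut))
  if (length(missing)) {
    stop("class map missing IDs: ", paste(missing, collapse = ", "))
  }
  unname(lut[ids])
}

#' Write an APC table as TSV
#'
#' Inverse of [read_apc()] for the TSV format: byte-for-byte round trip of
#' values, ordering, and class labels.
#'
#' @param apc an [apc_table()].
#' @param path output path.
#' @param class_column name for the class column when class labels are
#'   present.
#' @return `path`, invisibly.
#' @export
write_apc <- function(apc, path, class_column = "class") {
  stopifnot(inherits(apc, "apc_table"))
  out <- data.frame(id = apc$sequence_ids, stringsAsFactors = FALSE)
  if (!is.null(apc$class_labels)) out[[class_column]] <- apc$class_labels
  for (j in seq_along(apc$values)) {
    v <- apc$values[[j]]
    out[[apc$site_labels[j]]] <- if (is.numeric(v)) format(v, trim = TRUE) else v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Built-in amino-acid physicochemical property table
#'
#' One row per standard amino-acid one-letter symbol with five properties:
#' side-chain polarity class, side-chain acidity/basicity, hydropathy index
#' (Kyte-Doolittle scale), molecular weight of the free amino acid (Da),
#' and isoelectric point (pH units).  Polarity classes distinguish
#' aliphatic from aromatic non-polar residues (e.g. phenylalanine is
#' `"NonPolar_aromatic"`).  Users may override or extend the table (for
#' example to add a gap row) via [read_property_table()] or by editing the
#' returned data.frame.
#'
#' @return data.frame with rownames = symbols and columns `polarity`,
#'   `acidity_basicity`, `hydropathy`, `molecular_weight`,
#'   `isoelectric_point`.
#' @export
amino_acid_properties <- function() {
  sym <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  polarity <- c(A = "NonPolar_aliphatic", R = "Polar_basic",
                N = "Polar_uncharged", D = "Polar_acidic",
                C = "Polar_uncharged", Q = "Polar_uncharged",
                E = "Polar_acidic", G = "NonPolar_aliphatic",
                H = "Polar_basic", I = "NonPolar_aliphatic",
                L = "NonPolar_aliphatic", K = "Polar_basic",
                M = "NonPolar_aliphatic", F = "NonPolar_aromatic",
                P = "NonPolar_aliphatic", S = "Polar_uncharged",
                T = "Polar_uncharged", W = "NonPolar_aromatic",
                Y = "Polar_uncharged", V = "NonPolar_aliphatic")
  acidity <- c(A = "neutral", R = "basic", N = "neutral", D = "acidic",
               C = "neutral", Q = "neutral", E = "acidic", G = "neutral",
               H = "basic", I = "neutral", L = "neutral", K = "basic",
               M = "neutral", F = "neutral", P = "neutral", S = "neutral",
               T = "neutral", W = "neutral", Y = "neutral", V = "neutral")
  hydropathy <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                  E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                  M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                  Y = -1.3, V = 4.2)
  mw <- c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
          Q = 146.15, E = 147.13, G = 75.07, H = 155.16, I = 131.17,
          L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
          S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15)
  pi <- c(A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.07, Q = 5.65,
          E = 3.22, G = 5.97, H = 7.59, I = 6.02, L = 5.98, K = 9.74,
          M = 5.74, F = 5.48, P = 6.30, S = 5.68, T = 5.60, W = 5.89,
          Y = 5.66, V = 5.96)
  data.frame(polarity = unname(polarity[sym]),
             acidity_basicity = unname(acidity[sym]),
             hydropathy = unname(hydropathy[sym]),
             molecular_weight = unname(mw[sym]),
             isoelectric_point = unname(pi[sym]),
             row.names = sym, stringsAsFactors = FALSE)
}

#' Read a user property-table override
#'
#' CSV with columns `symbol, polarity, acidity_basicity, hydropathy,
#' molecular_weight, isoelectric_point`.
#'
#' @param path CSV path.
#' @return data.frame in the shape of [amino_acid_properties()].
#' @export
read_property_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("symbol", "polarity", "acidity_basicity", "hydropathy",
            "molecular_weight", "isoelectric_point")
  if (!all(need %in% names(df))) {
    stop("property table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$symbol)) stop("duplicate symbols in property table")
  out <- df[, need[-1]]
  rownames(out) <- df$symbol
  for (col in c("hydropathy", "molecular_weight", "isoelectric_point")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out
}

property_names <- c("polarity", "acidity_basicity", "hydropathy",
                    "molecular_weight", "isoelectric_point")

#' Expand a residue APC into a property APC (APPC)
#'
#' Replaces every residue cell by its 5-tuple of physicochemical
#' properties, turning an M x N residue table into an M x 5N mixed-mode
#' table.  Attribute keys are structured `(site, property_index)` pairs;
#' display labels concatenate the two, so the polarity (property 1) of site
#' "72" is labelled `"721"`.  Properties 1-2 (polarity,
#' acidity/basicity) are categorical; 3-5 (hydropathy, molecular weight,
#' isoelectric point) are numeric.  Class labels are carried through
#' unchanged.
#'
#' A gap symbol absent from `props` yields missing cells (`NA`) for that
#' residue's five attributes; rows with missing cells are excluded from
#' pairwise counts involving those attributes downstream.  Any other symbol
#' absent from `props` is an error naming the symbol and cell.
#'
#' @param apc an [apc_table()] of residue symbols.
#' @param props property table as from [amino_acid_properties()].
#' @param gap_symbol symbol treated as a gap (default `"-"`).
#' @return An [apc_table()] with `5 * N` attributes and structured
#'   `attr_meta`.
#' @export
expand_to_appc <- function(apc, props = amino_acid_properties(),
                           gap_symbol = "-") {
  stopifnot(inherits(apc, "apc_table"))
  if (any(apc$attribute_kinds != "categorical")) {
    stop("expand_to_appc expects a categorical residue APC")
  }
  m <- nrow(apc$values)
  known <- rownames(props)
  cols <- list()
  meta_site <- character(0)
  meta_prop <- integer(0)
  labels <- character(0)
  for (j in seq_along(apc$values)) {
    site <- apc$site_labels[j]
    res <- apc$values[[j]]
    bad <- setdiff(unique(res), c(known, gap_symbol))
    if (length(bad)) {
      row1 <- which(res == bad[1])[1]
      stop(sprintf(
        "expansion error: symbol '%s' (sequence '%s', site '%s') not in property table",
        bad[1], apc$sequence_ids[row1], site))
    }
    idx <- match(res, known)  # NA for gaps not present in props
    for (p in seq_along(property_names)) {
      v <- props[[property_names[p]]][idx]
      cols[[length(cols) + 1L]] <- v
      meta_site <- c(meta_site, site)
      meta_prop <- c(meta_prop, p)
      labels <- c(labels, paste0(site, p))
    }
  }
  values <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  names(values) <- labels
  kinds <- ifelse(meta_prop <= 2L, "categorical", "numeric")
  apc_table(values, sequence_ids = apc$sequence_ids, site_labels = labels,
            class_labels = apc$class_labels, attribute_kinds = kinds,
            attr_meta = data.frame(site = meta_site,
                                   property_index = meta_prop,
                                   stringsAsFactors = FALSE))
}

#' Build the event address table
#'
#' Maps every event (attribute, value) of an APC back to the exact list of
#' (sequence id, site label) cells holding it, so discovered ARs and ARAs
#' can be located in the original sequences.  Missing cells are skipped.
#'
#' @param apc an [apc_table()].
#' @return An object of class `address_table`: a named list keyed
#'   `"<site>=<value>"`, each element a data.frame with columns
#'   `sequence_id` and `site_label`.
#' @export
build_address_table <- function(apc) {
  stopifnot(inherits(apc, "apc_table"))
  at <- list()
  for (j in seq_along(apc$values)) {
    site <- apc$site_labels[j]
    v <- as.character(apc$values[[j]])
    ok <- !is.na(v)
    for (val in sort(unique(v[ok]), method = "radix")) {
      rows <- which(ok & v == val)
      at[[paste0(site, "=", val)]] <-
        data.frame(sequence_id = apc$sequence_ids[rows],
                   site_label = rep(site, length(rows)),
                   stringsAsFactors = FALSE)
    }
  }
  structure(at, class = "address_table")
}

#' Look up the sequences holding one event or an event pair
#'
#' With one event, returns its occurrence list.  With two events (an ARA),
#' returns the sequence IDs holding both.
#'
#' @param at an `address_table` from [build_address_table()].
#' @param event event key `"<site>=<value>"` or a `c(site, value)` pair.
#' @param event2 optional second event for an ARA query.
#' @return For one event, a data.frame of occurrences; for two, a character
#'   vector of sequence IDs (possibly empty).
#' @export
lookup_address <- function(at, event, event2 = NULL) {
  stopifnot(inherits(at, "address_table"))
  key <- function(e) if (length(e) == 2L) paste0(e[1], "=", e[2]) else e
  occ1 <- at[[key(event)]]
  if (is.null(occ1)) {
    occ1 <- data.frame(sequence_id = character(0), site_label = character(0),
                       stringsAsFactors = FALSE)
  }
  if (is.null(event2)) return(occ1)
  occ2 <- at[[key(event2)]]
  if (is.null(occ2)) return(character(0))
  intersect(occ1$sequence_id, occ2$sequence_id)
}
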