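#' Select the salient events on one principal component
#'
#' Events whose a-vectors project far from the center (zero) of a
#' component carry the associations that component captures.  An event is
#' selected when the magnitude of its projection coordinate exceeds
#' `stdev_factor` times the standard deviation of all projection
#' coordinates on that component.  Events at opposite extremes are both
#' reported with their signs, which is how opposing poles (e.g. two
#' alternative residues at the same site, each tied to a different class)
#' show up.
#'
#' @param pcs a `pc_decomp`.
#' @param k component index.
#' @param stdev_factor selection multiplier on the projection standard
#'   deviation (default 1.0).
#' @return data.frame with columns `event`, `attribute`, `value`,
#'   `projection`, `pole` (sign), sorted by `|projection|` descending
#'   (ties keep schema order).
#' @export
select_ars_on_pc <- function(pcs, k, stdev_factor = 1.0) {
  stopifnot(inherits(pcs, "pc_decomp"))
  proj <- pcs$projections[, k]
  s <- stats::sd(proj)
  ev <- pcs$schema$events
  sel <- if (is.na(s) || s == 0) rep(FALSE, length(proj)) else
    abs(proj) > stdev_factor * s
  out <- data.frame(event = ev$key[sel], attribute = ev$attribute[sel],
                    value = ev$value[sel], projection = proj[sel],
                    pole = sign(proj[sel]), stringsAsFactors = FALSE)
  out[order(-abs(out$projection)), , drop = FALSE]
}

#' Extract AR clusters from one re-projected residual matrix
#'
#' Builds a graph whose vertices are events and whose edges connect event
#' pairs of different attributes with `|residual| > threshold` in the
#' RSRV; the connected components of size >= 2 are the AR clusters — sets
#' of events that share strong associations within this component's
#' statistical space.  Each member is annotated with the sign of its
#' projection on the component (its pole), each edge with its residual.
#'
#' @param rsrv an `rsrv` from [reproject()].
#' @param threshold significance threshold on the re-projected residuals
#'   (default: the threshold carried by the source SRV, normally 1.96).
#' @return list with `k`, `clusters` (list of data.frames `event`,
#'   `attribute`, `value`, `pole`), and `edges` (data.frame `event_i`,
#'   `event_j`, `residual`, `cluster`).
#' @export
extract_clusters <- function(rsrv, threshold = rsrv$threshold) {
  stopifnot(inherits(rsrv, "rsrv"))
  ev <- rsrv$schema$events
  I <- nrow(ev)
  mat <- rsrv$matrix
  pairs <- which(upper.tri(mat) & abs(mat) > threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    same_attr <- ev$attr_index[pairs[, 1]] == ev$attr_index[pairs[, 2]]
    pairs <- pairs[!same_attr, , drop = FALSE]
  }
  if (!nrow(pairs)) {
    return(list(k = rsrv$k, clusters = list(),
                edges = data.frame(event_i = character(0),
                                   event_j = character(0),
                                   residual = numeric(0),
                                   cluster = integer(0),
                                   stringsAsFactors = FALSE)))
  }
  g <- igraph::graph_from_edgelist(
    cbind(ev$key[pairs[, 1]], ev$key[pairs[, 2]]), directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  # relabel clusters by schema order of their first member, for determinism
  first_seen <- vapply(seq_len(comp$no), function(cid) {
    min(match(names(membership)[membership == cid], ev$key))
  }, integer(1))
  relabel <- order(first_seen)
  newid <- match(membership, relabel)
  pole <- sign(rsrv$projection)
  clusters <- lapply(seq_len(comp$no), function(cid) {
    members <- names(membership)[newid == cid]
    ord <- order(match(members, ev$key))
    members <- members[ord]
    mi <- match(members, ev$key)
    data.frame(event = members, attribute = ev$attribute[mi],
               value = ev$value[mi], pole = pole[mi],
               stringsAsFactors = FALSE)
  })
  edges <- data.frame(event_i = ev$key[pairs[, 1]],
                      event_j = ev$key[pairs[, 2]],
                      residual = mat[pairs],
                      cluster = newid[match(ev$key[pairs[, 1]],
                                            names(membership))],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$cluster, -abs(edges$residual)), , drop = FALSE]
  rownames(edges) <- NULL
  list(k = rsrv$k, clusters = clusters, edges = edges)
}

#' Rank aligned sites by association strength and keep the strongest
#'
#' Scores every non-class site by the sum of squared residuals over all of
#' its events' associations, normalized by the site's event count, and
#' returns the `keep` highest-scoring site labels (ties broken by input
#' order).  Used to reduce wide APCs to their most association-rich sites
#' before decomposition, mirroring the removal of low-information aligned
#' sites in data preprocessing.
#'
#' @param srv an `srv_matrix`.
#' @param keep number of sites to retain (>= 2).
#' @return character vector of retained site labels, in input order.
#' @export
filter_sites <- function(srv, keep) {
  stopifnot(inherits(srv, "srv_matrix"))
  if (keep < 2L) stop("keep must be >= 2")
  ev <- srv$schema$events
  sites <- setdiff(srv$schema$attributes,
                   srv$schema$class_attribute[!is.na(srv$schema$class_attribute)])
  if (keep > length(sites)) {
    warning(sprintf("keep = %d exceeds site count %d; returning all sites",
                    keep, length(sites)))
    return(sites)
  }
  scores <- vapply(sites, function(site) {
    rows <- which(ev$attribute == site)
    sum(srv$sr[rows, , drop = FALSE]^2) / length(rows)
  }, numeric(1))
  ranked <- order(-scores)  # stable: ties keep input order
  keep_idx <- sort(ranked[seq_len(keep)])
  sites[keep_idx]
}

#' Subset an APC to a set of site labels
#'
#' @param apc an [apc_table()].
#' @param sites site labels to keep (input order preserved).
#' @return the reduced [apc_table()].
#' @export
subset_sites <- function(apc, sites) {
  stopifnot(inherits(apc, "apc_table"))
  keep <- apc$site_labels %in% sites
  if (sum(keep) < 2L) stop("fewer than two sites retained")
  meta <- apc$attr_meta
  if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  apc_table(apc$values[, keep, drop = FALSE],
            sequence_ids = apc$sequence_ids,
            site_labels = apc$site_labels[keep],
            class_labels = apc$class_labels,
            attribute_kinds = apc$attribute_kinds[keep],
            attr_meta = meta)
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with its default.  The
#' effective configuration is always written to the run manifest.
#'
#' @param discretize_method discretization method for numeric attributes.
#' @param bins bins per discretized attribute.
#' @param residual_mode `"adjusted"` or `"standardized"`.
#' @param threshold significance threshold on residuals.
#' @param component_rule `"above_mean_eigenvalue"` or `"top_n"`.
#' @param n_components component count for `top_n`.
#' @param stdev_factor selection multiplier in [select_ars_on_pc()].
#' @param use_class include class labels as an attribute when present
#'   (`FALSE` reproduces the unsupervised runs).
#' @param keep_sites optional site count for [filter_sites()] reduction
#'   before decomposition.
#' @param seed optional integer recorded in the manifest (the pipeline
#'   itself is deterministic; the seed is consumed by data generation).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(discretize_method = "equal_frequency",
                            bins = 3L,
                            residual_mode = "adjusted",
                            threshold = 1.96,
                            component_rule = "above_mean_eigenvalue",
                            n_components = NULL,
                            stdev_factor = 1.0,
                            use_class = TRUE,
                            keep_sites = NULL,
                            seed = NULL) {
  structure(list(discretize_method = discretize_method, bins = bins,
                 residual_mode = residual_mode, threshold = threshold,
                 component_rule = component_rule,
                 n_components = n_components,
                 stdev_factor = stdev_factor, use_class = use_class,
                 keep_sites = keep_sites, seed = seed),
            class = "pipeline_config")
}

#' Run the full discovery-and-disentanglement pipeline
#'
#' Chains the stages: discretize numeric attributes, enumerate the event
#' schema (with the class attribute when requested), build the frequency
#' matrix, convert to the SRV, decompose, retain components, and for each
#' retained component re-project and extract salient events and AR
#' clusters.  Every intermediate is returned, together with a manifest of
#' the effective configuration.
#'
#' @param apc an [apc_table()] (mixed-mode allowed).
#' @param config a [pipeline_config()].
#' @return An object of class `disentangled_result`: list with `apc`
#'   (the categorical table analysed), `schemes`, `schema`, `fm`, `srv`,
#'   `pcs`, `retained` (component indices), `components` (per retained k:
#'   `rsrv`, `selected` events, `clusters`, `edges`), `address`
#'   (an `address_table`), `manifest`.
#' @export
run_pipeline <- function(apc, config = pipeline_config()) {
  stopifnot(inherits(apc, "apc_table"))
  if (ncol(apc$values) < 2L) stop("stage schema: APC must have >= 2 attributes")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  disc <- stage("discretize",
                maybe_discretize(apc, method = config$discretize_method,
                                 bins = config$bins))
  cat_apc <- disc$apc
  schema <- stage("schema", event_schema(cat_apc,
                                         include_class = isTRUE(config$use_class)))
  fm <- stage("frequency_matrix", build_frequency_matrix(cat_apc, schema))
  srv <- stage("srv", compute_srv(fm, mode = config$residual_mode,
                                  threshold = config$threshold))
  if (!is.null(config$keep_sites)) {
    kept <- stage("filter_sites", filter_sites(srv, config$keep_sites))
    cat_apc <- stage("filter_sites", subset_sites(cat_apc, kept))
    schema <- stage("schema", event_schema(cat_apc,
                                           include_class = isTRUE(config$use_class)))
    fm <- stage("frequency_matrix", build_frequency_matrix(cat_apc, schema))
    srv <- stage("srv", compute_srv(fm, mode = config$residual_mode,
                                    threshold = config$threshold))
  }
  pcs <- stage("pcd", pcd(srv))
  retained <- stage("select_components",
                    select_components(pcs, rule = config$component_rule,
                                      n = config$n_components))
  components <- lapply(retained, function(k) {
    r <- stage("reproject", reproject(srv, pcs, k))
    cl <- stage("extract_clusters",
                extract_clusters(r, threshold = config$threshold))
    list(k = k, rsrv = r,
         selected = stage("select_ars",
                          select_ars_on_pc(pcs, k, config$stdev_factor)),
         clusters = cl$clusters, edges = cl$edges)
  })
  names(components) <- paste0("PC", retained)
  manifest <- c(unclass(config),
                list(M = nrow(cat_apc$values),
                     n_attributes = ncol(cat_apc$values),
                     I = schema$I,
                     retained_components = retained,
                     package_version = as.character(utils::packageVersion("arassoc"))))
  structure(list(apc = cat_apc, schemes = disc$schemes, schema = schema,
                 fm = fm, srv = srv, pcs = pcs, retained = retained,
                 components = components,
                 address = build_address_table(cat_apc),
                 manifest = manifest),
            class = "disentangled_result")
}

#' @export
print.disentangled_result <- function(x, ...) {
  cat(sprintf("disentangled_result: M = %d, I = %d events, mode = %s\n",
              x$manifest$M, x$schema$I, x$srv$mode))
  cat(sprintf("  retained components: %s\n",
              paste(x$retained, collapse = ", ")))
  for (cmp in x$components) {
    cat(sprintf("  PC%d: %d cluster(s), %d significant association(s)\n",
                cmp$k, length(cmp$clusters), nrow(cmp$edges)))
  }
  invisible(x)
}

#' Collect all significant association pairs of a result
#'
#' Flattens the suprathreshold edges of every retained re-projected
#' residual matrix into one table.
#'
#' @param result a `disentangled_result`.
#' @param ar_only drop pairs involving the class attribute.
#' @return data.frame with `component`, `event_i`, `event_j`, `residual`.
#' @export
significant_associations <- function(result, ar_only = FALSE) {
  stopifnot(inherits(result, "disentangled_result"))
  out <- do.call(rbind, lapply(result$components, function(cmp) {
    if (!nrow(cmp$edges)) return(NULL)
    cbind(component = cmp$k, cmp$edges[, c("event_i", "event_j", "residual")])
  }))
  if (is.null(out)) {
    return(data.frame(component = integer(0), event_i = character(0),
                      event_j = character(0), residual = numeric(0)))
  }
  rownames(out) <- NULL
  if (ar_only) {
    ca <- result$schema$class_attribute
    if (!is.na(ca)) {
      ev <- result$schema$events
      cls <- ev$key[ev$attribute == ca]
      out <- out[!(out$event_i %in% cls | out$event_j %in% cls), ,
                 drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}
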