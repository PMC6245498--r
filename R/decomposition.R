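#' Principal-component decomposition of the SRV
#'
#' Decomposes the statistical-residual vector space without mean-centering:
#' components are the right singular vectors of the SRV matrix itself
#' (equivalently, eigenvectors of `SRV' SRV`), and eigenvalues are the
#' squared singular values, sorted in descending order.  Skipping the
#' centering step is what makes the re-projection identity
#' `RSRV_k = SRV %*% PC_k %*% t(PC_k)` and the completeness property
#' `sum_k RSRV_k = SRV` hold exactly; a centered decomposition is
#' available for exploration via `center = TRUE` and is clearly
#' non-default (the re-projection identity then holds only for the
#' centered matrix).
#'
#' The sign of each component is fixed deterministically: the loading of
#' largest magnitude is made positive (ties broken by the first such
#' entry), so results do not depend on the LAPACK sign convention.
#'
#' @param srv an `srv_matrix` from [compute_srv()].
#' @param center mean-center the columns first (non-default; see above).
#' @return An object of class `pc_decomp`: list with `eigenvalues`
#'   (length I, non-negative, non-increasing), `components` (I x I matrix,
#'   column k = PC_k, orthonormal), `projections` (I x I matrix; entry
#'   (i, k) is the coordinate of a-vector i on PC_k), `schema`, `center`.
#' @export
pcd <- function(srv, center = FALSE) {
  stopifnot(inherits(srv, "srv_matrix"))
  S <- srv$sr
  I <- nrow(S)
  if (I < 2L) stop("SRV must have I >= 2 events")
  if (center) S <- sweep(S, 2L, colMeans(S))
  if (all(S == 0)) {
    warning("SRV is all zero; returning zero eigenvalues with identity basis")
    comp <- diag(I)
    dimnames(comp) <- list(rownames(srv$sr), paste0("PC", seq_len(I)))
    proj <- srv$sr %*% comp
    colnames(proj) <- colnames(comp)
    return(structure(list(eigenvalues = rep(0, I), components = comp,
                          projections = proj, schema = srv$schema,
                          center = center),
                     class = "pc_decomp"))
  }
  sv <- svd(S)
  comp <- sv$v
  # deterministic sign: largest-|loading| entry positive per component
  for (k in seq_len(I)) {
    pivot <- which.max(abs(comp[, k]))
    if (comp[pivot, k] < 0) comp[, k] <- -comp[, k]
  }
  dimnames(comp) <- list(rownames(srv$sr), paste0("PC", seq_len(I)))
  proj <- srv$sr %*% comp
  colnames(proj) <- colnames(comp)
  structure(list(eigenvalues = sv$d^2, components = comp,
                 projections = proj, schema = srv$schema, center = center),
            class = "pc_decomp")
}

#' @export
print.pc_decomp <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("pc_decomp: %d components; top eigenvalues: %s\n",
              length(ev),
              paste(format(utils::head(ev, 5), digits = 4), collapse = ", ")))
  invisible(x)
}

#' Re-project one component back to residual space
#'
#' Computes `RSRV_k = SRV %*% PC_k %*% t(PC_k)`: the rank-one part of the
#' residual structure captured by component k alone.  Row i of the result
#' is the projection coordinate of a-vector i on PC_k times `t(PC_k)` —
#' the residual strengths of that event's associations as seen through
#' this component.
#'
#' @param srv the source `srv_matrix`.
#' @param pcs the matching `pc_decomp`.
#' @param k component index in `1..I`.
#' @return An object of class `rsrv`: list with `k`, `matrix` (I x I),
#'   `projection` (coordinates of all a-vectors on PC_k), `component`
#'   (PC_k), `threshold` and `mode` (inherited), `schema`.
#' @export
reproject <- function(srv, pcs, k) {
  stopifnot(inherits(srv, "srv_matrix"), inherits(pcs, "pc_decomp"))
  I <- nrow(srv$sr)
  if (!(k >= 1L && k <= I)) stop("component index k out of range 1..", I)
  v <- pcs$components[, k]
  proj <- drop(srv$sr %*% v)
  mat <- tcrossprod(proj, v)
  dimnames(mat) <- dimnames(srv$sr)
  structure(list(k = k, matrix = mat, projection = proj, component = v,
                 threshold = srv$threshold, mode = srv$mode,
                 schema = srv$schema),
            class = "rsrv")
}

#' Select which components to retain
#'
#' `top_n` keeps the first `n` components; `above_mean_eigenvalue` keeps
#' every component whose eigenvalue strictly exceeds the mean eigenvalue
#' (the Kaiser-style rule on the uncentered spectrum).  With a flat
#' spectrum `above_mean_eigenvalue` selects nothing.
#'
#' @param pcs a `pc_decomp`.
#' @param rule `"above_mean_eigenvalue"` or `"top_n"`.
#' @param n component count for `top_n` (clipped to I with a warning).
#' @return integer vector of retained component indices (ascending).
#' @export
select_components <- function(pcs, rule = c("above_mean_eigenvalue", "top_n"),
                              n = NULL) {
  stopifnot(inherits(pcs, "pc_decomp"))
  rule <- match.arg(rule)
  I <- length(pcs$eigenvalues)
  if (rule == "top_n") {
    if (is.null(n)) stop("rule 'top_n' requires n")
    if (n > I) {
      warning(sprintf("n = %d exceeds component count %d; clipping", n, I))
      n <- I
    }
    return(seq_len(n))
  }
  which(pcs$eigenvalues > mean(pcs$eigenvalues))
}

#' Export a decomposition as CSV files
#'
#' Writes `eigenvalues.csv` (component, eigenvalue) and
#' `pc_coordinates.csv` (per event: attribute, value, then the projection
#' coordinate on every component) into `dir`.
#'
#' @param pcs a `pc_decomp`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pcd_csv <- function(pcs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(component = seq_along(pcs$eigenvalues),
                              eigenvalue = pcs$eigenvalues),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  ev <- pcs$schema$events
  out <- cbind(ev[, c("attribute", "value")],
               as.data.frame(pcs$projections))
  utils::write.csv(out, file.path(dir, "pc_coordinates.csv"),
                   row.names = FALSE)
  invisible(dir)
}
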