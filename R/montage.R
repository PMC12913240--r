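#' 64-channel 10-20 EEG montage
#'
#' Builds the 64-channel montage used throughout the package: standard
#' 10-20/10-10 labels (including Fz, Pz, CPz and the mastoids M1/M2),
#' idealized unit-sphere positions, a symmetric channel-adjacency graph, and
#' nested reduced caps of 8, 16 and 32 sensors that respect 10-20 topology
#' (each contains Fz and Pz, and 8 < 16 < 32 < 64 are nested).
#'
#' Adjacency is built on the 2-D azimuthal projection of the electrode
#' positions by Delaunay triangulation with edges longer than 1.5 times the
#' median edge length pruned (falling back to a distance-threshold rule when
#' the `deldir` package is unavailable). M1/M2 sit off the scalp and are kept
#' out of the adjacency graph; they serve re-referencing only.
#'
#' @return An `lg_montage` list with elements `labels`, `pos` (64 x 3 matrix),
#'   `pos2d` (64 x 2 projected), `adjacency` (64 x 64 logical), `subsets`
#'   (named list of label vectors for 8/16/32/64 caps), `ref_labels`
#'   (`c("M1", "M2")`) and `online_ref` (`"CPz"`).
#' @export
#' @examples
#' mon <- montage_ant64()
#' sum(mon$adjacency) / 2   # number of neighbor pairs
montage_ant64 <- function() {
  labels <- .montage64_labels
  pos <- cbind(x = .montage64_x, y = .montage64_y, z = .montage64_z)
  rownames(pos) <- labels
  pos2d <- project_azimuthal(pos)
  ref_labels <- c("M1", "M2")
  scalp <- setdiff(labels, ref_labels)
  adjacency <- matrix(FALSE, length(labels), length(labels),
                      dimnames = list(labels, labels))
  adjacency[scalp, scalp] <- build_adjacency(pos2d[scalp, , drop = FALSE])

  subsets <- list(
    `8`  = c("Fz", "Cz", "Pz", "C3", "C4", "P3", "P4", "Oz"),
    `16` = c("Fz", "Cz", "Pz", "C3", "C4", "P3", "P4", "Oz",
             "Fp1", "Fp2", "F3", "F4", "F7", "F8", "P7", "P8"),
    `32` = c("Fz", "Cz", "Pz", "C3", "C4", "P3", "P4", "Oz",
             "Fp1", "Fp2", "F3", "F4", "F7", "F8", "P7", "P8",
             "T7", "T8", "O1", "O2", "FC1", "FC2", "FC5", "FC6",
             "CP1", "CP2", "CP5", "CP6", "POz", "AF3", "AF4", "FCz"),
    `64` = labels
  )
  stopifnot(all(unlist(subsets) %in% labels))

  structure(list(labels = labels, pos = pos, pos2d = pos2d,
                 adjacency = adjacency, subsets = subsets,
                 ref_labels = ref_labels, online_ref = "CPz"),
            class = "lg_montage")
}

# Azimuthal equidistant projection from the vertex: preserves arc length from
# Cz, the standard flattening for sensor-level topography work.
project_azimuthal <- function(pos) {
  theta <- acos(pmin(1, pmax(-1, pos[, 3])))   # inclination from vertex
  rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  scale <- ifelse(rho > 1e-12, theta / rho, 0)
  cbind(x = pos[, 1] * scale, y = pos[, 2] * scale)
}

build_adjacency <- function(pos2d) {
  n <- nrow(pos2d)
  adj <- matrix(FALSE, n, n, dimnames = list(rownames(pos2d), rownames(pos2d)))
  edges <- NULL
  if (requireNamespace("deldir", quietly = TRUE) && n >= 3) {
    dd <- deldir::deldir(pos2d[, 1], pos2d[, 2], suppressMsge = TRUE)
    edges <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
  }
  if (is.null(edges)) {
    d <- as.matrix(stats::dist(pos2d))
    diag(d) <- Inf
    thr <- 1.5 * median(apply(d, 1, min))
    idx <- which(d <= thr, arr.ind = TRUE)
    edges <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  }
  len <- sqrt(rowSums((pos2d[edges[, 1], , drop = FALSE] -
                         pos2d[edges[, 2], , drop = FALSE])^2))
  keep <- len <= 1.5 * median(len)
  edges <- edges[keep, , drop = FALSE]
  adj[edges] <- TRUE
  adj[edges[, 2:1, drop = FALSE]] <- TRUE
  diag(adj) <- FALSE
  adj
}

#' Restrict a montage to one of its nested sensor subsets
#'
#' @param montage An [montage_ant64()] montage.
#' @param n_sensors One of 8, 16, 32, 64 (or a character vector of labels).
#' @return An `lg_montage` restricted to those channels, adjacency recomputed
#'   on the retained positions.
#' @export
montage_subset <- function(montage, n_sensors) {
  keep <- if (is.character(n_sensors)) n_sensors
          else montage$subsets[[as.character(n_sensors)]]
  if (is.null(keep)) stopf("no %s-sensor subset defined", n_sensors)
  if (!all(keep %in% montage$labels)) stopf("subset labels missing from montage")
  idx <- match(keep, montage$labels)
  pos <- montage$pos[idx, , drop = FALSE]
  pos2d <- montage$pos2d[idx, , drop = FALSE]
  ref <- intersect(montage$ref_labels, keep)
  scalp <- setdiff(keep, ref)
  adjacency <- matrix(FALSE, length(keep), length(keep),
                      dimnames = list(keep, keep))
  adjacency[scalp, scalp] <- build_adjacency(pos2d[scalp, , drop = FALSE])
  structure(list(labels = keep, pos = pos, pos2d = pos2d,
                 adjacency = adjacency,
                 subsets = montage$subsets[
                   vapply(montage$subsets, function(s) all(s %in% keep), TRUE)],
                 ref_labels = ref, online_ref = montage$online_ref),
            class = "lg_montage")
}

# Channels entering analysis (everything but the mastoid references).
analysis_channels <- function(montage) {
  setdiff(montage$labels, montage$ref_labels)
}

# Adjacency as a 0-based neighbor list for the compiled TFCE/cluster code,
# restricted to `channels` in that order.
adjacency_list <- function(montage, channels = analysis_channels(montage)) {
  A <- montage$adjacency[channels, channels, drop = FALSE]
  lapply(seq_along(channels), function(i) as.integer(which(A[i, ])) - 1L)
}
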