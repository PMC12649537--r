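#' Nine-cluster electrode maps
#'
#' The architecture groups scalp electrodes into nine spatial clusters that
#' roughly track major cortical territories. Cluster order is fixed:
#' prefrontal, frontal, left temporal, central, right temporal, left parietal,
#' mid-parietal, right parietal, occipital. A map is a strict partition of a
#' montage's labels: every cluster non-empty, no label in two clusters.
#'
#' `default_cluster_map()` ships three editable defaults: `"10-20-32ch"` (the
#' 32-channel layout used by consumer-grade caps), `"10-20-62ch"` (a dense
#' 62-channel layout) and `"toy-9ch"` (one channel per cluster, used by the
#' synthetic benchmark). The 32/62-channel assignments are reconstructed from
#' standard 10-20 label prefixes (Fp*/AF* prefrontal, F* frontal, T7/FT7/TP7
#' left temporal, FC*/C* central, P/CP left-right split parietal, *z midline,
#' O*/PO*/CB* occipital); users wanting a different grouping can edit the map
#' file (see [write_cluster_map()]).
#'
#' @param montage_name one of `"10-20-32ch"`, `"10-20-62ch"`, `"toy-9ch"`.
#' @return A `cluster_map` object: list with `montage_name` and `clusters`
#'   (named list of 9 character vectors in fixed cluster order).
#' @export
default_cluster_map <- function(montage_name = c("10-20-32ch", "10-20-62ch", "toy-9ch")) {
  montage_name <- match.arg(montage_name)
  clusters <- switch(
    montage_name,
    "10-20-32ch" = list(
      prefrontal     = c("Fp1", "Fp2", "AF3", "AF4"),
      frontal        = c("F7", "F3", "Fz", "F4", "F8"),
      left_temporal  = c("T7"),
      central        = c("FC5", "FC1", "C3", "Cz", "C4", "FC2", "FC6"),
      right_temporal = c("T8"),
      left_parietal  = c("CP5", "CP1", "P3", "P7"),
      mid_parietal   = c("Pz"),
      right_parietal = c("CP2", "CP6", "P4", "P8"),
      occipital      = c("PO3", "O1", "Oz", "O2", "PO4")),
    "10-20-62ch" = list(
      prefrontal     = c("FP1", "FPZ", "FP2", "AF3", "AF4"),
      frontal        = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8"),
      left_temporal  = c("FT7", "T7", "TP7"),
      central        = c("FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6",
                         "C5", "C3", "C1", "CZ", "C2", "C4", "C6"),
      right_temporal = c("FT8", "T8", "TP8"),
      left_parietal  = c("CP5", "CP3", "CP1", "P7", "P5", "P3", "P1"),
      mid_parietal   = c("CPZ", "PZ", "POZ"),
      right_parietal = c("CP2", "CP4", "CP6", "P2", "P4", "P6", "P8"),
      occipital      = c("PO7", "PO5", "PO3", "PO4", "PO6", "PO8",
                         "CB1", "O1", "OZ", "O2", "CB2")),
    "toy-9ch" = list(
      prefrontal     = c("Fp1"),
      frontal        = c("F3"),
      left_temporal  = c("T7"),
      central        = c("Cz"),
      right_temporal = c("T8"),
      left_parietal  = c("P3"),
      mid_parietal   = c("Pz"),
      right_parietal = c("P4"),
      occipital      = c("O1")))
  cluster_map(montage_name, clusters)
}

#' Fixed cluster order used throughout the package
#' @return Character vector of the nine cluster names in canonical order.
#' @export
cluster_order <- function() {
  c("prefrontal", "frontal", "left_temporal", "central", "right_temporal",
    "left_parietal", "mid_parietal", "right_parietal", "occipital")
}

#' Construct a cluster map
#'
#' @param montage_name text identifier of the montage.
#' @param clusters named list of character vectors; names must be the nine
#'   canonical cluster names (any order accepted, stored in canonical order).
#' @return A `cluster_map` object.
#' @export
cluster_map <- function(montage_name, clusters) {
  if (!is.list(clusters)) stop("clusters must be a named list")
  ord <- cluster_order()
  if (!setequal(names(clusters), ord)) {
    stop("clusters must be named exactly: ", paste(ord, collapse = ", "))
  }
  clusters <- lapply(clusters[ord], as.character)
  structure(list(montage_name = as.character(montage_name), clusters = clusters),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %s: %d channels in 9 clusters\n",
              x$montage_name, length(unlist(x$clusters))))
  for (nm in names(x$clusters)) {
    cat(sprintf("  %-14s %s\n", nm, paste(x$clusters[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' Validate a cluster map against a montage's channel labels
#'
#' Checks every structural invariant: exactly nine clusters in canonical
#' order, no empty cluster, no channel assigned twice, and every mapped
#' channel present in `montage_labels`. Violations are reported, not raised.
#'
#' @param map a `cluster_map`.
#' @param montage_labels character vector of the montage's channel labels.
#' @return List with `ok` (logical) and `violations` (character vector).
#' @export
validate_cluster_map <- function(map, montage_labels) {
  if (!inherits(map, "cluster_map")) stop("map must be a cluster_map")
  if (length(montage_labels) == 0) stop("montage_labels must be non-empty")
  v <- character(0)
  if (length(map$clusters) != 9L) {
    v <- c(v, sprintf("expected 9 clusters, found %d", length(map$clusters)))
  }
  for (nm in names(map$clusters)) {
    if (length(map$clusters[[nm]]) == 0) v <- c(v, paste0("empty cluster: ", nm))
  }
  all_ch <- unlist(map$clusters, use.names = FALSE)
  dup <- unique(all_ch[duplicated(all_ch)])
  for (ch in dup) v <- c(v, paste0("channel in multiple clusters: ", ch))
  missing <- setdiff(all_ch, montage_labels)
  for (ch in missing) v <- c(v, paste0("channel not in montage: ", ch))
  list(ok = length(v) == 0L, violations = v)
}

#' Split a recording into the nine per-cluster sub-recordings
#'
#' Each sub-recording keeps only the rows of the cluster's channels, in the
#' within-cluster order given by the map; the sample axis is untouched. The
#' nine channel sets together reproduce exactly the channels covered by the
#' map (partition property).
#'
#' @param recording a [raw_recording()].
#' @param map a `cluster_map` valid for the recording's labels.
#' @return Named list (canonical cluster order) of `raw_recording` objects.
#' @export
split_by_cluster <- function(recording, map) {
  rep_ <- validate_cluster_map(map, recording$channel_labels)
  if (!rep_$ok) stop("invalid cluster map: ", rep_$violations[1])
  out <- lapply(names(map$clusters), function(nm) {
    ch <- map$clusters[[nm]]
    raw_recording(recording$data[ch, , drop = FALSE], recording$fs, ch,
                  recording$subject_id, recording$trial_id, recording$ratings)
  })
  names(out) <- names(map$clusters)
  out
}

#' Read / write cluster maps as YAML or JSON config files
#'
#' File layout: `montage_name`, then `clusters:` mapping cluster name to a
#' list of channel labels. Format is picked from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return `read_cluster_map` returns a `cluster_map`;
#'   `write_cluster_map` returns `path` invisibly.
#' @export
read_cluster_map <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(x$montage_name) || is.null(x$clusters)) {
    stop("cluster map file must contain 'montage_name' and 'clusters'")
  }
  cluster_map(x$montage_name, lapply(x$clusters, as.character))
}

#' @param map a `cluster_map` to serialize.
#' @rdname read_cluster_map
#' @export
write_cluster_map <- function(map, path) {
  x <- list(montage_name = map$montage_name, clusters = map$clusters)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Channel labels of a montage's default map
#' @inheritParams default_cluster_map
#' @return Character vector of channel labels in cluster order.
#' @export
montage_labels <- function(montage_name = "10-20-32ch") {
  unlist(default_cluster_map(montage_name)$clusters, use.names = FALSE)
}
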