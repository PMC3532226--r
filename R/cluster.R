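#' Pairwise Pearson similarity of standardized profiles
#'
#' Builds the n-by-n matrix of Pearson correlation coefficients between the
#' value vectors of standardized profiles. The duplicated +50 endpoint (the
#' same aboral point as -50) is dropped before correlating so that no grid
#' position is double-weighted.
#'
#' @param profiles list of `standard_profile`s with equal grid lengths.
#'   Labels are taken from list names, else composed as `{gene}:{stage}`
#'   from profile metadata.
#' @param drop_duplicate_endpoint drop the final (+50) grid point; default
#'   `TRUE`.
#' @return A `similarity_matrix`: symmetric numeric matrix with unit
#'   diagonal and profile labels as dimnames.
#' @export
similarity_matrix <- function(profiles, drop_duplicate_endpoint = TRUE) {
  if (length(profiles) < 2L) {
    lq_abort("lq_argument_error", "need at least 2 profiles")
  }
  lens <- vapply(profiles, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    lq_abort("lq_argument_error", "profiles have unequal grid lengths")
  }
  labels <- names(profiles)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(profiles, function(p) {
      g <- attr(p, "gene")
      if (is.null(g) || is.na(g)) "" else sprintf("%s:%s", g, format(attr(p, "stage")))
    }, character(1))
    labels[!nzchar(labels)] <- sprintf("profile%02d", which(!nzchar(labels)))
  }
  V <- vapply(profiles, function(p) p$value, numeric(lens[1]))
  if (drop_duplicate_endpoint) V <- V[-nrow(V), , drop = FALSE]
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0)) {
    lq_abort("lq_zero_variance",
             sprintf("constant profile(s): %s",
                     paste(labels[sds == 0], collapse = ", ")),
             offenders = labels[sds == 0])
  }
  S <- stats::cor(V)
  dimnames(S) <- list(labels, labels)
  structure(S, class = c("similarity_matrix", "matrix"))
}

#' Cluster profiles by average-linkage on Pearson similarity
#'
#' Converts similarity to distance (`d = 1 - r`), agglomerates with
#' unweighted average linkage (UPGMA) and cuts the tree at cophenetic
#' distance `1 - cut_similarity`. Groups are numbered in dendrogram leaf
#' order (group 1 is the topmost leaf's group).
#'
#' @param matrix a [similarity_matrix()].
#' @param cut_similarity similarity level at which the dendrogram is cut;
#'   default 0.6.
#' @return A `cluster_tree`: list with `merge`, `height` (cophenetic
#'   distances, as in [stats::hclust()]), `order` (leaf order), `labels`,
#'   `groups` (integer vector named by label, numbered in leaf order),
#'   `cut_similarity` and the underlying `hclust` object.
#' @export
cluster_profiles <- function(matrix, cut_similarity = 0.6) {
  d <- stats::as.dist(1 - matrix)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = 1 - cut_similarity)
  # renumber groups in dendrogram leaf order
  first_seen <- unique(raw[hc$order])
  groups <- match(raw, first_seen)
  names(groups) <- names(raw)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, groups = groups,
                 cut_similarity = cut_similarity, hclust = hc),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d profiles, %d group(s) at similarity %.2f\n",
              length(x$labels), max(x$groups), x$cut_similarity))
  for (g in seq_len(max(x$groups))) {
    cat(sprintf("  group %d: %s\n", g,
                paste(x$labels[x$groups == g], collapse = ", ")))
  }
  invisible(x)
}

#' Read a directory of standardized profiles
#'
#' Reads every `*.csv` in a directory with [read_standard_profile()]. Labels
#' are parsed from filenames of the form `{gene}_{stage}.csv` and displayed
#' as `{gene}:{stage}`; other filenames are used verbatim.
#'
#' @param dir directory path.
#' @return Named list of `standard_profile`s.
#' @export
read_profile_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) lq_abort("lq_argument_error", "no profile CSVs found")
  profiles <- lapply(files, read_standard_profile)
  base <- sub("\\.csv$", "", basename(files))
  names(profiles) <- ifelse(grepl("_", base),
                            sub("_([^_]+)$", ":\\1", base), base)
  profiles
}

#' Write clustering results
#'
#' Writes a `groups.tsv` (label, group, leaf order), a `merges.tsv` (the
#' agglomeration table with cophenetic distances and similarities), and a
#' `heatmap.png` showing the profiles in dendrogram leaf order with the
#' black-to-green expression colormap.
#'
#' @param profiles the profile list that was clustered.
#' @param tree a [cluster_profiles()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cluster_results <- function(profiles, tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- data.frame(label = tree$labels, group = as.integer(tree$groups),
                       leaf_position = match(seq_along(tree$labels), tree$order))
  utils::write.table(groups, file.path(dir, "groups.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  merges <- data.frame(node = seq_len(nrow(tree$merge)),
                       left = tree$merge[, 1], right = tree$merge[, 2],
                       distance = tree$height,
                       similarity = 1 - tree$height)
  utils::write.table(merges, file.path(dir, "merges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  grDevices::png(file.path(dir, "heatmap.png"), width = 900, height = 60 +
                   28 * length(profiles))
  plot_profile_heatmap(profiles, tree)
  grDevices::dev.off()
  invisible(dir)
}

#' Heatmap of standardized profiles in dendrogram order
#'
#' Base-graphics heatmap: one row per profile, ordered by the dendrogram
#' leaves, intensity scaled from black (no expression) to bright green
#' (maximal expression).
#'
#' @inheritParams write_cluster_results
#' @export
plot_profile_heatmap <- function(profiles, tree) {
  ord <- tree$order
  V <- t(vapply(profiles[ord], function(p) p$value,
                numeric(nrow(profiles[[1]]))))
  pal <- grDevices::colorRampPalette(c("black", "green"))(256)
  op <- graphics::par(mar = c(4, 10, 1, 1))
  on.exit(graphics::par(op))
  grid <- profiles[[1]]$position
  graphics::image(x = grid, y = seq_len(nrow(V)), z = t(V[rev(seq_len(nrow(V))), ]),
                  col = pal, zlim = c(0, 100), axes = FALSE,
                  xlab = "normalized cell layer position", ylab = "")
  graphics::axis(1)
  graphics::axis(2, at = seq_len(nrow(V)), labels = rev(tree$labels[ord]),
                 las = 2, tick = FALSE, cex.axis = 0.8)
  invisible(NULL)
}
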