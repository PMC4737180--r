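#' Median profiles of a sample's clusters
#'
#' For each cluster with at least `min_members` assigned events, computes
#' the per-bin median profile on the signed-offset bin grid of untruncated
#' members: bins are aligned by signed offset from each block's border, and
#' truncated members contribute only to the bins they possess. Clusters
#' below `min_members` are skipped (reported in `skipped`).
#'
#' @param assignments data.frame `event_id`, `row`, `col` for one sample.
#' @param profiles named list of the sample's `meth_profile` objects.
#' @param min_members minimal cluster size (default 5).
#' @param sample_id sample label stamped into the median ids
#'   (`sample:row:col`).
#' @return list with `medians` (list of `meth_profile` objects, one per
#'   kept cluster, with attribute `n_members`) and `skipped` (data.frame
#'   `row`, `col`, `n`).
#' @export
median_profiles <- function(assignments, profiles, min_members = 5L,
                            sample_id = "sample") {
  stopifnot(all(assignments$event_id %in% names(profiles)))
  clusters <- unique(assignments[, c("row", "col")])
  clusters <- clusters[order(clusters$row, clusters$col), , drop = FALSE]
  medians <- list()
  skipped <- NULL
  for (i in seq_len(nrow(clusters))) {
    sel <- assignments$row == clusters$row[i] & assignments$col == clusters$col[i]
    members <- profiles[assignments$event_id[sel]]
    if (length(members) < min_members) {
      skipped <- rbind(skipped, data.frame(row = clusters$row[i],
                                           col = clusters$col[i],
                                           n = length(members)))
      next
    }
    tab <- profile_bin_table(members)
    med <- stats::aggregate(value ~ block + offset, tab, median)
    ie <- med[med$block == "IE", ]
    ei <- med[med$block == "EI", ]
    ie <- ie[order(ie$offset), ]
    ei <- ei[order(ei$offset), ]
    p <- new_profile(sprintf("%s:%d:%d", sample_id, clusters$row[i],
                             clusters$col[i]),
                     c(ie$value, ei$value),
                     ie_pre = sum(ie$offset < 0), ie_post = sum(ie$offset >= 0),
                     ei_pre = sum(ei$offset < 0), ei_post = sum(ei$offset >= 0),
                     bin_size = members[[1]]$bin_size)
    attr(p, "n_members") <- length(members)
    attr(p, "sample") <- sample_id
    attr(p, "cluster") <- c(row = clusters$row[i], col = clusters$col[i])
    medians[[p$event_id]] <- p
  }
  list(medians = medians,
       skipped = if (is.null(skipped)) data.frame(row = integer(0),
                                                  col = integer(0),
                                                  n = integer(0)) else skipped)
}

#' Meta-group cluster median profiles across samples
#'
#' Complete-linkage hierarchical clustering of cluster median profiles
#' using unbanded normalized DTW as the distance, cut into exactly
#' `n_groups` super-groups. Groups are ordered by increasing mean
#' methylation of their member medians and labeled with Roman numerals
#' (I = lowest methylation).
#'
#' @param medians list of median `meth_profile` objects (typically pooled
#'   over samples from [median_profiles()]).
#' @param n_groups number of super-groups (default 4).
#' @return a `super_grouping` object: list with `hclust`, `groups`
#'   (data.frame `id`, `sample`, `row`, `col`, `group`, `label`),
#'   `n_groups`, `medians`.
#' @export
meta_cluster <- function(medians, n_groups = 4L) {
  if (length(medians) < n_groups)
    stop(sprintf("meta_cluster: %d medians < %d groups", length(medians),
                 n_groups))
  D <- dtw_distance_matrix(medians, band_radius = NULL)
  stopifnot(isSymmetric(D))
  hc <- hclust(as.dist(D), method = "complete")
  raw <- cutree(hc, k = n_groups)
  lvl <- vapply(medians, function(p) mean(p$values), numeric(1))
  grp_level <- tapply(lvl, raw, mean)
  ord <- order(grp_level)                   # group 1 = lowest methylation
  relabel <- match(seq_len(n_groups), ord)
  group <- relabel[raw]
  ids <- names(medians)
  samples <- vapply(medians, function(p) {
    s <- attr(p, "sample"); if (is.null(s)) sub(":.*$", "", p$event_id) else s
  }, character(1))
  cl <- t(vapply(medians, function(p) {
    cc <- attr(p, "cluster")
    if (is.null(cc)) {
      parts <- strsplit(p$event_id, ":")[[1]]
      cc <- c(row = as.numeric(parts[2]), col = as.numeric(parts[3]))
    }
    as.numeric(cc)
  }, c(row = 0, col = 0)))
  structure(list(
    hclust = hc,
    groups = data.frame(id = ids, sample = samples,
                        row = cl[, "row"], col = cl[, "col"],
                        group = group,
                        label = as.character(utils::as.roman(group)),
                        stringsAsFactors = FALSE),
    n_groups = as.integer(n_groups), medians = medians),
    class = "super_grouping")
}

#' @export
print.super_grouping <- function(x, ...) {
  cat(sprintf("Super-grouping of %d cluster medians into %d groups:\n",
              nrow(x$groups), x$n_groups))
  print(table(x$groups$label, x$groups$sample))
  invisible(x)
}

#' Write the meta-grouping dendrogram as Newick
#'
#' Leaves are labeled `sample:row:col`.
#'
#' @param path output file.
#' @param grouping a `super_grouping`.
#' @export
write_dendrogram <- function(path, grouping) {
  phy <- ape::as.phylo(grouping$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Map a sample's events to super-groups
#'
#' @param assignments the sample's `event_id`/`row`/`col` table.
#' @param grouping a `super_grouping`.
#' @param sample_id the sample's label in the grouping.
#' @return data.frame `event_id`, `group` (Roman label); events assigned to
#'   clusters that produced no median (below `min_members`) are dropped.
#' @export
supergroup_membership <- function(assignments, grouping, sample_id) {
  g <- grouping$groups[grouping$groups$sample == sample_id, ]
  idx <- match(paste(assignments$row, assignments$col),
               paste(g$row, g$col))
  keep <- !is.na(idx)
  data.frame(event_id = assignments$event_id[keep],
             group = g$label[idx[keep]], stringsAsFactors = FALSE)
}

#' Cross-sample membership sharing between super-groups
#'
#' For every pair of samples, computes over the events covered in both the
#' fraction assigned to super-group `g1` in one sample and `g2` in the
#' other; edges below `min_edge` are omitted. Also returns the per-sample
#' membership ratio map (fraction of covered events per group, rows
#' summing to 1).
#'
#' @param groupings named list (one entry per sample) of data.frames
#'   `event_id`, `group` (see [supergroup_membership()]).
#' @param min_edge minimal reported sharing fraction (default 0.05).
#' @return list with `edges` (data.frame `sample1`, `group1`, `sample2`,
#'   `group2`, `weight`, `n_common`) and `ratios` (data.frame `sample`,
#'   `group`, `ratio`).
#' @export
membership_sharing <- function(groupings, min_edge = 0.05) {
  stopifnot(length(groupings) >= 2, !is.null(names(groupings)))
  samples <- names(groupings)
  all_groups <- sort(unique(unlist(lapply(groupings, function(g) g$group))))
  ratios <- NULL
  for (s in samples) {
    g <- groupings[[s]]
    for (gr in all_groups) {
      ratios <- rbind(ratios, data.frame(
        sample = s, group = gr, ratio = mean(g$group == gr),
        stringsAsFactors = FALSE))
    }
  }
  edges <- NULL
  for (a in seq_len(length(samples) - 1L)) {
    for (b in seq(a + 1L, length(samples))) {
      ga <- groupings[[samples[a]]]
      gb <- groupings[[samples[b]]]
      common <- intersect(ga$event_id, gb$event_id)
      if (length(common) == 0L) next
      la <- ga$group[match(common, ga$event_id)]
      lb <- gb$group[match(common, gb$event_id)]
      for (g1 in all_groups) {
        for (g2 in all_groups) {
          w <- sum(la == g1 & lb == g2) / length(common)
          if (w >= min_edge)
            edges <- rbind(edges, data.frame(
              sample1 = samples[a], group1 = g1,
              sample2 = samples[b], group2 = g2,
              weight = w, n_common = length(common),
              stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(edges))
    edges <- data.frame(sample1 = character(0), group1 = character(0),
                        sample2 = character(0), group2 = character(0),
                        weight = numeric(0), n_common = integer(0))
  list(edges = edges, ratios = ratios)
}

#' Shared-membership fraction between two super-groups
#'
#' Fraction of events, over those covered in both samples of each pair,
#' that sit in group `g1` in one sample and `g2` in the other (summed over
#' both orientations, averaged over sample pairs). Used to verify that
#' low- and high-methylation groups rarely exchange members.
#'
#' @param groupings as in [membership_sharing()].
#' @param g1,g2 group labels.
#' @return average cross-pair sharing fraction.
#' @export
shared_membership_fraction <- function(groupings, g1, g2) {
  samples <- names(groupings)
  fr <- c()
  for (a in seq_len(length(samples) - 1L)) {
    for (b in seq(a + 1L, length(samples))) {
      ga <- groupings[[samples[a]]]
      gb <- groupings[[samples[b]]]
      common <- intersect(ga$event_id, gb$event_id)
      if (length(common) == 0L) next
      la <- ga$group[match(common, ga$event_id)]
      lb <- gb$group[match(common, gb$event_id)]
      fr <- c(fr, (sum(la == g1 & lb == g2) + sum(la == g2 & lb == g1)) /
                length(common))
    }
  }
  if (length(fr) == 0L) NA_real_ else mean(fr)
}
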