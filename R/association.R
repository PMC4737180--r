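#' Mann-Whitney test of a cluster property against the background
#'
#' Two-sided rank-sum test of the property values of one cluster against a
#' background set (by convention the entire AS event set of the sample, the
#' cluster included, which makes the test slightly conservative for large
#' clusters). The exact null distribution is used when the product of the
#' group sizes is at most 400 and there are no ties; otherwise the normal
#' approximation with tie correction. The reported direction is the sign of
#' the median difference.
#'
#' @param cluster_values,background_values numeric vectors (>= 3 finite
#'   values each).
#' @return list with `U` (Mann-Whitney statistic of the cluster sample),
#'   `p` (two-sided), `direction` (`"high"`, `"low"`, or `NA` when the
#'   medians are equal or all values are tied).
#' @export
test_property <- function(cluster_values, background_values) {
  x <- cluster_values[is.finite(cluster_values)]
  y <- background_values[is.finite(background_values)]
  if (length(x) < 3L || length(y) < 3L)
    stop("test_property: need at least 3 finite values per side")
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1, direction = NA_character_))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400) && !ties
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact))
  dmed <- median(x) - median(y)
  direction <- if (dmed > 0) "high" else if (dmed < 0) "low" else NA_character_
  list(U = unname(ht$statistic), p = min(ht$p.value, 1), direction = direction)
}

#' Bin-wise border test of a cluster's profiles
#'
#' Tests each border bin of the cluster against the background, with bins
#' aligned by signed offset from the border (truncated profiles contribute
#' only the bins they have; only offsets covered by at least `min_n`
#' events on both sides are tested). P-values are Benjamini-Hochberg
#' adjusted across the tested bins; the cluster is flagged
#' significant-high (-low) when more than `frac` of the tested bins are
#' significant with that same direction.
#'
#' @param cluster_profiles,background_profiles lists of `meth_profile`
#'   objects (background conventionally includes the cluster).
#' @param frac minimal fraction of same-direction significant bins
#'   (strict inequality; default 0.8).
#' @param level FDR level (default 0.05).
#' @param min_n minimal events per side covering a bin (default 3).
#' @return list with `flag` (`"high"`, `"low"`, or `"none"`) and `bins`
#'   (data.frame `block`, `offset`, `U`, `p`, `q`, `direction`,
#'   `significant`).
#' @export
binwise_border_test <- function(cluster_profiles, background_profiles,
                                frac = 0.8, level = 0.05, min_n = 3L) {
  ct <- profile_bin_table(cluster_profiles)
  bt <- profile_bin_table(background_profiles)
  key <- function(d) paste(d$block, d$offset)
  bins <- unique(ct[, c("block", "offset")])
  out <- NULL
  for (i in seq_len(nrow(bins))) {
    kk <- paste(bins$block[i], bins$offset[i])
    cv <- ct$value[key(ct) == kk]
    bv <- bt$value[key(bt) == kk]
    if (sum(is.finite(cv)) < min_n || sum(is.finite(bv)) < min_n) next
    tp <- test_property(cv, bv)
    out <- rbind(out, data.frame(block = bins$block[i], offset = bins$offset[i],
                                 U = tp$U, p = tp$p, direction = tp$direction,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out) || nrow(out) == 0L)
    return(list(flag = "none", bins = data.frame()))
  adj <- fdr_adjust(out$p, level)
  out$q <- adj$qvals
  out$significant <- adj$flags & !is.na(out$direction)
  n_tested <- nrow(out)
  n_high <- sum(out$significant & out$direction == "high", na.rm = TRUE)
  n_low <- sum(out$significant & out$direction == "low", na.rm = TRUE)
  flag <- if (n_high / n_tested > frac) "high"
          else if (n_low / n_tested > frac) "low" else "none"
  list(flag = flag, bins = out[, c("block", "offset", "U", "p", "q",
                                   "direction", "significant")])
}

#' Hypergeometric motif enrichment and depletion
#'
#' With `X ~ Hypergeometric(N = bg_n, K = bg_hits, n = cluster_n)`,
#' `p_enrich = P[X >= cluster_hits]` and `p_deplete = P[X <= cluster_hits]`.
#' The background conventionally contains the cluster.
#'
#' @param cluster_hits events in the cluster matching the motif.
#' @param cluster_n cluster size.
#' @param bg_hits,bg_n background hits and size.
#' @return list with `p_enrich` and `p_deplete`.
#' @export
motif_enrichment <- function(cluster_hits, cluster_n, bg_hits, bg_n) {
  stopifnot(cluster_hits <= cluster_n, bg_hits <= bg_n)
  if (cluster_n > bg_n)
    stop("motif_enrichment: cluster larger than background")
  list(p_enrich = phyper(cluster_hits - 1, bg_hits, bg_n - bg_hits, cluster_n,
                         lower.tail = FALSE),
       p_deplete = phyper(cluster_hits, bg_hits, bg_n - bg_hits, cluster_n))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals p-values in `[0, 1]`.
#' @param level FDR level for the significance flags (default 0.05).
#' @return list with `qvals` (step-up adjusted) and `flags`
#'   (`qvals <= level`); empty input gives empty output.
#' @export
fdr_adjust <- function(pvals, level = 0.05) {
  if (length(pvals) == 0L)
    return(list(qvals = numeric(0), flags = logical(0)))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  q <- p.adjust(pvals, method = "BH")
  list(qvals = q, flags = !is.na(q) & q <= level)
}

#' IUPAC motif hits in border sequences
#'
#' Scans each sequence for at least one match of each motif's IUPAC
#' consensus on either strand (the motif or its reverse complement on the
#' given sequence).
#'
#' @param sequences named character vector or `Biostrings::DNAStringSet`
#'   (names conventionally `<event_id>|IE` / `<event_id>|EI`).
#' @param motifs a `motif_set` from [read_motifs()] (columns `name`,
#'   `consensus`).
#' @return logical matrix, sequences x motifs.
#' @export
scan_motif_hits <- function(sequences, motifs) {
  seqs <- if (inherits(sequences, "DNAStringSet")) sequences
          else Biostrings::DNAStringSet(unlist(sequences))
  hits <- matrix(FALSE, length(seqs), nrow(motifs),
                 dimnames = list(names(seqs), motifs$name))
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(gsub("U", "T", motifs$consensus[i]))
    fwd <- Biostrings::vcountPattern(pat, seqs, fixed = FALSE)
    rev_ <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                      seqs, fixed = FALSE)
    hits[, i] <- (fwd + rev_) > 0
  }
  hits
}

#' Per-cluster property association report
#'
#' Tests each numeric property within each cluster against the background
#' (all events of the sample, cluster included) with [test_property()],
#' then adjusts p-values per property across clusters (Benjamini-Hochberg).
#' Direction is reported only for significant associations.
#'
#' @param assignments data.frame `event_id`, `row`, `col`.
#' @param events validated event data.frame containing the property
#'   columns.
#' @param properties character vector of numeric columns in `events` to
#'   test (default: `psi`, `fpkm`, `tss_distance` where present, plus any
#'   extra numeric columns).
#' @param level FDR level (default 0.05).
#' @param min_cluster minimal cluster size to test (default 3).
#' @return data.frame with columns `row`, `col`, `property`, `n`, `U`, `p`,
#'   `q`, `significant`, `direction`.
#' @export
association_report <- function(assignments, events, properties = NULL,
                               level = 0.05, min_cluster = 3L) {
  if (is.null(properties)) {
    skip <- c(.event_required, "psi", "fpkm", "tss_distance")
    extra <- names(events)[vapply(events, is.numeric, logical(1))]
    properties <- c(intersect(c("psi", "fpkm", "tss_distance"), names(events)),
                    setdiff(extra, skip))
  }
  ev <- merge(assignments, events, by = "event_id")
  clusters <- unique(ev[, c("row", "col")])
  clusters <- clusters[order(clusters$row, clusters$col), , drop = FALSE]
  out <- NULL
  for (prop in properties) {
    bg <- events[[prop]]
    rows <- NULL
    for (i in seq_len(nrow(clusters))) {
      sel <- ev$row == clusters$row[i] & ev$col == clusters$col[i]
      cv <- ev[[prop]][sel]
      if (sum(is.finite(cv)) < min_cluster) next
      tp <- test_property(cv, bg)
      rows <- rbind(rows, data.frame(
        row = clusters$row[i], col = clusters$col[i], property = prop,
        n = sum(is.finite(cv)), U = tp$U, p = tp$p,
        direction = tp$direction, stringsAsFactors = FALSE))
    }
    if (is.null(rows)) next
    adj <- fdr_adjust(rows$p, level)       # family: one property, all clusters
    rows$q <- adj$qvals
    rows$significant <- adj$flags
    rows$direction[!rows$significant] <- NA_character_
    out <- rbind(out, rows)
  }
  if (is.null(out)) return(data.frame())
  out[, c("row", "col", "property", "n", "U", "p", "q", "significant",
          "direction")]
}

#' Per-cluster motif enrichment report
#'
#' Counts, for each cluster, motif and border side, the events whose
#' border sequence matches the motif, and tests enrichment and depletion
#' against the background (all events with a sequence for that side) with
#' the hypergeometric test. P-values are adjusted per motif and side
#' across clusters; the enrichment and depletion flags are mutually
#' exclusive.
#'
#' @param assignments data.frame `event_id`, `row`, `col`.
#' @param sequences named `DNAStringSet` or character vector; names are
#'   `<event_id>|IE` or `<event_id>|EI`.
#' @param motifs a `motif_set`.
#' @param level FDR level (default 0.05).
#' @return data.frame with columns `row`, `col`, `motif`, `side`,
#'   `cluster_hits`, `cluster_n`, `bg_hits`, `bg_n`, `p_enrich`,
#'   `p_deplete`, `q_enrich`, `q_deplete`, `flag`.
#' @export
motif_report <- function(assignments, sequences, motifs, level = 0.05) {
  hits <- scan_motif_hits(sequences, motifs)
  nm <- rownames(hits)
  side <- sub("^.*\\|", "", nm)
  event <- sub("\\|[^|]*$", "", nm)
  clusters <- unique(assignments[, c("row", "col")])
  clusters <- clusters[order(clusters$row, clusters$col), , drop = FALSE]
  out <- NULL
  for (sd in unique(side)) {
    hs <- hits[side == sd, , drop = FALSE]
    evs <- event[side == sd]
    covered <- intersect(evs, assignments$event_id)
    hs <- hs[match(covered, evs), , drop = FALSE]
    bg_n <- length(covered)
    asg <- assignments[match(covered, assignments$event_id), ]
    for (mo in colnames(hs)) {
      bg_hits <- sum(hs[, mo])
      rows <- NULL
      for (i in seq_len(nrow(clusters))) {
        sel <- asg$row == clusters$row[i] & asg$col == clusters$col[i]
        if (!any(sel)) next
        he <- motif_enrichment(sum(hs[sel, mo]), sum(sel), bg_hits, bg_n)
        rows <- rbind(rows, data.frame(
          row = clusters$row[i], col = clusters$col[i], motif = mo, side = sd,
          cluster_hits = sum(hs[sel, mo]), cluster_n = sum(sel),
          bg_hits = bg_hits, bg_n = bg_n,
          p_enrich = he$p_enrich, p_deplete = he$p_deplete,
          stringsAsFactors = FALSE))
      }
      if (is.null(rows)) next
      qe <- fdr_adjust(rows$p_enrich, level)   # family: one motif x side
      qd <- fdr_adjust(rows$p_deplete, level)
      rows$q_enrich <- qe$qvals
      rows$q_deplete <- qd$qvals
      rows$flag <- ifelse(qe$flags & (!qd$flags | rows$p_enrich <= rows$p_deplete),
                          "enriched",
                          ifelse(qd$flags, "depleted", "none"))
      out <- rbind(out, rows)
    }
  }
  if (is.null(out)) data.frame() else out
}
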