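#' Hypergeometric gene-set enrichment against a custom background
#'
#' Upper-tail hypergeometric test of the overlap between a called gene set
#' and an annotation gene set, both restricted to a user-supplied
#' background universe first.
#'
#' @param called Character vector of called gene ids (subset of
#'   `background`).
#' @param annotation Character vector of annotated gene ids (intersected
#'   with `background` before testing).
#' @param background Character vector: the gene universe.
#' @return List with `overlap`, `n_called`, `n_annotation`, `n_background`
#'   and the upper-tail `p` (probability of an overlap at least as large).
#' @export
hypergeometric_enrichment <- function(called, annotation, background) {
  background <- unique(background)
  called <- unique(intersect(called, background))
  annotation <- unique(intersect(annotation, background))
  if (length(annotation) == 0L) stop("annotation has no genes in background")
  if (length(called) == 0L) stop("called set has no genes in background")
  overlap <- length(intersect(called, annotation))
  m <- length(annotation)
  n <- length(background) - m
  k <- length(called)
  p <- stats::phyper(overlap - 1, m, n, k, lower.tail = FALSE)
  list(overlap = overlap, n_called = k, n_annotation = m,
       n_background = length(background), p = p)
}

# SegmentSet data frame (chrom, start 0-based, end half-open) -> GRanges
.segments_to_granges <- function(segments) {
  stopifnot(all(c("chrom", "start", "end") %in% names(segments)),
            all(segments$start < segments$end))
  GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1L,
                              end = segments$end))
}

# per-segment base pairs covered by a (reduced) track
.overlap_bp <- function(seg_gr, track_gr) {
  track_gr <- GenomicRanges::reduce(track_gr)
  hits <- GenomicRanges::findOverlaps(seg_gr, track_gr)
  bp <- numeric(length(seg_gr))
  if (length(hits) > 0) {
    inter <- IRanges::pintersect(seg_gr[S4Vectors::queryHits(hits)],
                                 track_gr[S4Vectors::subjectHits(hits)])
    contrib <- tapply(BiocGenerics::width(inter),
                      S4Vectors::queryHits(hits), sum)
    bp[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  bp
}

#' Monte-Carlo preferential-overlap test of case segments against a track
#'
#' Tests whether case-labeled genomic segments overlap a track more than
#' expected when case/control labels are randomly reassigned over the fixed
#' segment set (preserving the number of cases). The statistic is the total
#' base pairs of case segments covered by the track (`stat = "bp"`) or the
#' number of case segments touched (`stat = "count"`); the one-sided
#' p-value is `(1 + #\{null >= observed\}) / (1 + n_mc)`.
#'
#' @param segments Data frame (chrom, start, end, label) with labels
#'   `case`/`control`; BED convention, 0-based half-open.
#' @param track Data frame (chrom, start, end) of track intervals.
#' @param n_mc Number of Monte-Carlo label permutations (>= 100; 1000 in
#'   production runs).
#' @param seed Integer seed.
#' @param stat `"bp"` (default) or `"count"`.
#' @return List with `observed_stat`, `mc_p`, `n_mc`, `stat`, `n_case`,
#'   `n_control` and `flag` (`"empty_track"` when the track has no
#'   intervals, in which case `mc_p = 1`).
#' @export
mc_overlap_test <- function(segments, track, n_mc = 1000L, seed = 1L,
                            stat = c("bp", "count")) {
  stat <- match.arg(stat)
  stopifnot(n_mc >= 100, all(segments$label %in% c("case", "control")))
  n_case <- sum(segments$label == "case")
  n_control <- sum(segments$label == "control")
  stopifnot(n_case >= 1, n_control >= 1)
  if (nrow(track) == 0L) {
    return(list(observed_stat = 0, mc_p = 1, n_mc = as.integer(n_mc),
                stat = stat, n_case = n_case, n_control = n_control,
                flag = "empty_track"))
  }
  seg_gr <- .segments_to_granges(segments)
  per_seg <- .overlap_bp(seg_gr, .segments_to_granges(track))
  if (stat == "count") per_seg <- as.numeric(per_seg > 0)
  is_case <- segments$label == "case"
  obs <- sum(per_seg[is_case])
  # canonical order: permutation draws hit the same overlap amounts no
  # matter how segments were ordered or chromosomes named on input
  per_seg <- per_seg[order(segments$start, segments$end, segments$label)]
  set.seed(seed)
  n_seg <- nrow(segments)
  hits <- 0L
  for (i in seq_len(n_mc)) {
    idx <- sample.int(n_seg, n_case)
    if (sum(per_seg[idx]) >= obs) hits <- hits + 1L
  }
  list(observed_stat = obs, mc_p = (1 + hits) / (1 + n_mc),
       n_mc = as.integer(n_mc), stat = stat,
       n_case = n_case, n_control = n_control, flag = NA_character_)
}

#' Stouffer-merge p-values of replicate tracks
#'
#' Replicate tracks (e.g. duplicate ChIP experiments for one factor) are
#' reduced to one p-value via the Stouffer Z-score combination.
#'
#' @param p_values One-tailed p-values of the replicate tracks.
#' @return Combined p-value.
#' @export
merge_replicate_tracks <- function(p_values) {
  stouffer_combine(p_values)
}

#' BH adjustment within track batches
#'
#' Applies Benjamini-Hochberg independently within each batch of tracks
#' (tracks are batched by origin, e.g. TF ChIP vs chromatin-state vs DNase
#' vs histone tracks).
#'
#' @param results Data frame with a `track_id` column and a p-value column.
#' @param batch Named character vector or data frame (`track_id`, `batch`)
#'   assigning every track to exactly one batch.
#' @param p_col Name of the p-value column to adjust (default `"merged_p"`,
#'   falling back to `"mc_p"` when absent).
#' @return `results` with `batch` and `q` columns added.
#' @export
batched_fdr <- function(results, batch, p_col = NULL) {
  if (is.data.frame(batch)) {
    batch <- stats::setNames(batch$batch, batch$track_id)
  }
  if (is.null(p_col)) {
    p_col <- if ("merged_p" %in% names(results)) "merged_p" else "mc_p"
  }
  b <- batch[results$track_id]
  if (any(is.na(b))) {
    stop("track(s) without batch assignment: ",
         paste(results$track_id[is.na(b)], collapse = ", "))
  }
  results$batch <- unname(b)
  results$q <- stats::ave(results[[p_col]], results$batch,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  results
}

#' Run the overlap test over a collection of tracks
#'
#' Applies [mc_overlap_test()] to every track, Stouffer-merges replicate
#' tracks sharing a `replicate_of` target, and computes batched q-values.
#'
#' @param segments Case/control segment data frame.
#' @param tracks Named list of track data frames.
#' @param batch Named character vector mapping track (or merged target)
#'   names to batches.
#' @param replicate_of Optional named character vector mapping track names
#'   to a shared target name; tracks of one target are merged.
#' @param n_mc,seed,stat Passed to [mc_overlap_test()].
#' @return Data frame: track_id, observed_stat, mc_p, merged_p, batch, q.
#' @export
run_overlap_suite <- function(segments, tracks, batch,
                              replicate_of = NULL, n_mc = 1000L, seed = 1L,
                              stat = "bp") {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  res <- lapply(names(tracks), function(tn) {
    r <- mc_overlap_test(segments, tracks[[tn]], n_mc = n_mc, seed = seed,
                         stat = stat)
    data.frame(track_id = tn, observed_stat = r$observed_stat,
               mc_p = r$mc_p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (!is.null(replicate_of)) {
    target <- ifelse(res$track_id %in% names(replicate_of),
                     replicate_of[res$track_id], res$track_id)
    merged <- vapply(split(res$mc_p, target), merge_replicate_tracks,
                     numeric(1))
    res <- data.frame(track_id = names(merged),
                      observed_stat = as.vector(tapply(res$observed_stat,
                                                       target, sum)),
                      mc_p = NA_real_, merged_p = as.vector(merged),
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    res$merged_p <- res$mc_p
  }
  batched_fdr(res, batch, p_col = "merged_p")
}

#' Gene segments (TSS to gene end) labeled by DCG status
#'
#' Builds the case/control segment set for the overlap tests from a gene
#' coordinate table and a called gene list: called genes are `case`, all
#' other genes `control`.
#'
#' @param gene_coords Data frame with gene_id, chrom, start, end (0-based
#'   half-open).
#' @param called_genes Character vector of case gene ids.
#' @return Segment data frame (chrom, start, end, label, gene_id).
#' @export
label_gene_segments <- function(gene_coords, called_genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(gene_coords)))
  data.frame(chrom = gene_coords$chrom, start = gene_coords$start,
             end = gene_coords$end,
             label = ifelse(gene_coords$gene_id %in% called_genes,
                            "case", "control"),
             gene_id = gene_coords$gene_id, stringsAsFactors = FALSE)
}
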