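# Interval-level annotation of ATAC-seq peaks: target-gene assignment,
# chromatin-state collapsing at the peak summit, reciprocal overlap,
# score-quantile reference-peak selection, TF-group collapsing from bound
# sites, and a bedtools-fisher style base-pair enrichment test.
#
# File I/O uses BED conventions (0-based half-open); in-memory intervals
# are GRanges (1-based closed). narrowPeak summit = BED start + offset.

#' Read a narrowPeak / BED file into GRanges
#'
#' @param path file path (plain text, tab-separated, no header).
#' @return a \code{GRanges}; narrowPeak adds mcols \code{name},
#'   \code{score} and \code{summit_offset}; BED keeps \code{name} and
#'   \code{score} when present.
#' @export
readNarrowPeak <- function(path) {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 10) stop("narrowPeak requires 10 columns: ", path)
    gr <- GenomicRanges::GRanges(df[[1]],
        IRanges::IRanges(df[[2]] + 1L, df[[3]]))
    gr$name <- df[[4]]
    gr$score <- df[[5]]
    gr$summit_offset <- df[[10]]
    names(gr) <- make.unique(as.character(df[[4]]))
    gr
}

#' @rdname readNarrowPeak
#' @export
readBed <- function(path) {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df[[1]],
        IRanges::IRanges(df[[2]] + 1L, df[[3]]))
    if (ncol(df) >= 4) {
        gr$name <- df[[4]]
        names(gr) <- make.unique(as.character(df[[4]]))
    }
    if (ncol(df) >= 5) gr$score <- df[[5]]
    if (ncol(df) >= 6) GenomicRanges::strand(gr) <- ifelse(
        df[[6]] %in% c("+", "-"), df[[6]], "*")
    gr
}

#' Write GRanges as BED
#'
#' @param gr a \code{GRanges}.
#' @param path output path; coordinates are converted to 0-based half-open.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     name = if (!is.null(gr$name)) gr$name else
                         if (!is.null(names(gr))) names(gr) else ".",
                     score = if (!is.null(gr$score)) gr$score else 0,
                     strand = as.character(GenomicRanges::strand(gr)))
    df$strand[df$strand == "*"] <- "."
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Assign each peak its putative target gene
#'
#' Finds the closest transcription start site within \code{max_dist} of
#' each peak (distance 0 if the TSS lies inside the peak, otherwise the gap
#' length). Distance ties - including several TSSs inside one peak - are
#' resolved by the highest reference expression, then lexicographic gene
#' ID. Peaks with no TSS in range are left unassigned (omitted).
#'
#' @param peaks \code{GRanges} of peaks (names used as peak IDs).
#' @param tss \code{GRanges} of width-1, strand-resolved TSS positions with
#'   mcols \code{gene_id} and \code{expression} (per-gene maximum reference
#'   expression used for tie-breaking).
#' @param max_dist maximum peak-TSS distance in bp (default 100000).
#' @return data.frame with \code{peak_id}, \code{gene_id}, \code{distance}.
#' @export
assignTargetGene <- function(peaks, tss, max_dist = 100000) {
    stopifnot(all(GenomicRanges::width(tss) == 1),
              !is.null(tss$gene_id), !is.null(tss$expression))
    if (is.null(names(peaks))) names(peaks) <- paste0("peak", seq_along(peaks))
    hits <- GenomicRanges::findOverlaps(peaks, tss, maxgap = max_dist,
                                        ignore.strand = TRUE)
    if (length(hits) == 0)
        return(data.frame(peak_id = character(0), gene_id = character(0),
                          distance = integer(0)))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    d <- GenomicRanges::distance(peaks[q], tss[s], ignore.strand = TRUE)
    cand <- data.frame(peak_id = names(peaks)[q],
                       gene_id = as.character(tss$gene_id[s]),
                       expression = tss$expression[s],
                       distance = d, stringsAsFactors = FALSE)
    cand <- cand[cand$distance <= max_dist, , drop = FALSE]
    ord <- order(cand$peak_id, cand$distance, -cand$expression, cand$gene_id)
    cand <- cand[ord, ]
    best <- cand[!duplicated(cand$peak_id), c("peak_id", "gene_id",
                                              "distance")]
    rownames(best) <- NULL
    best
}

#' The 12-to-5 chromatin-state collapsing map
#'
#' Active promoters stay uncollapsed; enhancers absorb genic enhancers and
#' promoter-flanking regions; the three bivalent states merge; the three
#' transcription states merge; and the two polycomb states merge.
#'
#' @return named character vector mapping the 12 source states to the 5
#'   collapsed states.
#' @export
chromatinStateMap <- function() {
    c(TssA = "Active Promoter",
      TssAFlnk = "Enhancer", EnhG = "Enhancer", Enh = "Enhancer",
      TssBiv = "Bivalent Chromatin", BivFlnk = "Bivalent Chromatin",
      EnhBiv = "Bivalent Chromatin",
      Tx = "Transcription", TxWk = "Transcription",
      TxFlnk = "Transcription",
      ReprPC = "Repressed Polycomb", ReprPCWk = "Repressed Polycomb")
}

#' Collapse peak chromatin states at the summit
#'
#' A peak's chromatin state is the label of the state interval containing
#' its summit (start + \code{summit_offset}), collapsed into the 5 broad
#' categories. Summits falling in an annotation gap or in an excluded
#' state (ZNF/Rpts, Het, Quies) are \code{"unassigned"}.
#'
#' @param peaks \code{GRanges} with mcol \code{summit_offset}.
#' @param states \code{GRanges} with mcol \code{name} giving the source
#'   chromatin-state label.
#' @param map source-to-collapsed map (default
#'   \code{\link{chromatinStateMap}}).
#' @return data.frame with \code{peak_id}, \code{state} (source label or
#'   NA), \code{collapsed_state}.
#' @export
collapseChromatinState <- function(peaks, states, map = chromatinStateMap()) {
    off <- peaks$summit_offset
    if (is.null(off)) stop("peaks must carry a 'summit_offset' mcol")
    if (any(off < 0 | off >= GenomicRanges::width(peaks)))
        stop("summit outside peak bounds")
    if (is.null(names(peaks))) names(peaks) <- paste0("peak", seq_along(peaks))
    summit <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
        IRanges::IRanges(GenomicRanges::start(peaks) + off, width = 1))
    hits <- GenomicRanges::findOverlaps(summit, states, select = "first",
                                        ignore.strand = TRUE)
    src <- ifelse(is.na(hits), NA_character_,
                  as.character(states$name[hits]))
    collapsed <- ifelse(!is.na(src) & src %in% names(map), map[src],
                        "unassigned")
    data.frame(peak_id = names(peaks), state = src,
               collapsed_state = unname(collapsed),
               stringsAsFactors = FALSE)
}

#' Reciprocal-overlap interval matching
#'
#' Pair (a, b) matches iff the overlap length is at least
#' \code{fraction} of the length of a AND of b (bedtools
#' \code{intersect -f -r} semantics; the boundary is inclusive).
#'
#' @param track_a,track_b \code{GRanges}.
#' @param fraction required reciprocal overlap fraction (default 0.25).
#' @return data.frame of matched index pairs \code{idx_a}, \code{idx_b}
#'   with the overlap width.
#' @export
reciprocalOverlap <- function(track_a, track_b, fraction = 0.25) {
    hits <- GenomicRanges::findOverlaps(track_a, track_b,
                                        ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
        track_a[q], track_b[s], ignore.strand = TRUE))
    keep <- ov >= fraction * GenomicRanges::width(track_a)[q] &
        ov >= fraction * GenomicRanges::width(track_b)[s]
    data.frame(idx_a = q[keep], idx_b = s[keep], overlap = ov[keep])
}

#' Select reference peaks by score quantile
#'
#' Removes peaks overlapping any exclusion track, bins the survivors into
#' \code{n_quantiles} equal-count bins by ascending score (any remainder is
#' spread over the top bins; score ties broken by coordinate) and retains
#' bins \code{keep_from} and above.
#'
#' @param peaks \code{GRanges} with mcol \code{score}.
#' @param excluded list of \code{GRanges} exclusion tracks (blacklist,
#'   inactive chromatin states, ...); may be empty.
#' @param n_quantiles number of score bins (default 20).
#' @param keep_from first retained bin (default 8, i.e. bins 8..20).
#' @return list with \code{peaks} (retained \code{GRanges} with mcol
#'   \code{score_quantile}) and \code{assignment} (data.frame over all
#'   surviving peaks: \code{peak_id}, \code{score_quantile},
#'   \code{retained}).
#' @export
selectReferencePeaks <- function(peaks, excluded = list(), n_quantiles = 20,
                                 keep_from = 8) {
    stopifnot(!is.null(peaks$score))
    if (is.null(names(peaks))) names(peaks) <- paste0("peak", seq_along(peaks))
    drop <- rep(FALSE, length(peaks))
    for (ex in excluded)
        drop <- drop | GenomicRanges::countOverlaps(peaks, ex,
                                                    ignore.strand = TRUE) > 0
    surv <- peaks[!drop]
    m <- length(surv)
    if (m < n_quantiles)
        stop("fewer surviving peaks (", m, ") than quantiles (",
             n_quantiles, ")")
    ord <- order(surv$score, as.character(GenomicRanges::seqnames(surv)),
                 GenomicRanges::start(surv), GenomicRanges::end(surv))
    base <- m %/% n_quantiles
    rem <- m %% n_quantiles
    sizes <- rep(base, n_quantiles)
    if (rem > 0)
        sizes[seq(n_quantiles - rem + 1, n_quantiles)] <-
            sizes[seq(n_quantiles - rem + 1, n_quantiles)] + 1
    qbin <- integer(m)
    qbin[ord] <- rep(seq_len(n_quantiles), sizes)
    surv$score_quantile <- qbin
    keep <- qbin >= keep_from
    list(peaks = surv[keep],
         assignment = data.frame(peak_id = names(surv),
                                 score_quantile = qbin,
                                 retained = keep,
                                 stringsAsFactors = FALSE))
}

#' Collapse motifs into TF groups by bound-site overlap
#'
#' Motifs whose predicted bound-site sets are near-identical cannot be
#' distinguished and are collapsed: the pairwise Jaccard similarity matrix
#' over bound-site sets is computed, motifs are clustered by the Euclidean
#' distance between similarity-profile rows with average linkage, and the
#' tree is cut at height \code{cut_height}. The cut is absolute by default:
#' unrelated motifs sit at a profile distance of about \eqn{\sqrt{2}}
#' (driven by their own diagonal entries) regardless of the number of
#' motifs, so an absolute 0.75 separates unrelated motifs while merging
#' near-clones; a cut relative to the maximum merge height is available via
#' \code{relative = TRUE}. Motifs with empty site sets become singleton
#' groups with a warning.
#'
#' @param bound_sites named list of per-motif bound-site ID vectors (a
#'   shared site universe).
#' @param cut_height tree-cut height (default 0.75).
#' @param relative interpret \code{cut_height} as a fraction of the
#'   maximum merge height instead of an absolute height (default FALSE).
#' @param families optional named vector mapping motif -> TF family, used
#'   to categorize multi-motif groups as \code{"family"} (all members in
#'   one family) or \code{"complex"}.
#' @return data.frame with \code{motif}, \code{group}, \code{group_size},
#'   \code{category} (\code{single}/\code{family}/\code{complex}); groups
#'   partition the motif set.
#' @export
collapseTFGroups <- function(bound_sites, cut_height = 0.75,
                             relative = FALSE, families = NULL) {
    stopifnot(length(bound_sites) >= 2, !is.null(names(bound_sites)))
    motifs <- names(bound_sites)
    empty <- lengths(bound_sites) == 0
    if (any(empty))
        warning("motif(s) with empty bound-site sets placed in singleton ",
                "groups: ", paste(motifs[empty], collapse = ", "))
    use <- motifs[!empty]
    grp <- integer(length(motifs))
    names(grp) <- motifs
    if (length(use) >= 2) {
        sets <- bound_sites[use]
        m <- length(use)
        J <- diag(1, m)
        for (i in seq_len(m - 1)) for (k in seq(i + 1, m)) {
            inter <- length(intersect(sets[[i]], sets[[k]]))
            uni <- length(union(sets[[i]], sets[[k]]))
            J[i, k] <- J[k, i] <- if (uni > 0) inter / uni else 0
        }
        hc <- hclust(dist(J), method = "average")
        h <- if (relative) cut_height * max(hc$height) else cut_height
        cl <- if (max(hc$height) <= h) rep(1L, m) else cutree(hc, h = h)
        grp[use] <- cl
    } else if (length(use) == 1) {
        grp[use] <- 1L
    }
    nxt <- max(grp) + 1L
    for (mo in motifs[empty]) {
        grp[mo] <- nxt
        nxt <- nxt + 1L
    }
    sizes <- table(grp)
    category <- vapply(motifs, function(mo) {
        g <- grp[mo]
        if (sizes[[as.character(g)]] == 1) return("single")
        members <- motifs[grp == g]
        if (!is.null(families) && all(members %in% names(families)) &&
                length(unique(families[members])) == 1) "family" else
            "complex"
    }, character(1))
    data.frame(motif = motifs, group = unname(grp),
               group_size = as.integer(sizes[as.character(grp)]),
               category = unname(category), stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Base-pair Fisher test between two interval tracks
#'
#' Builds the bedtools-fisher style 2x2 base-pair table (covered by both,
#' A only, B only, neither = genome minus the union), summed over
#' chromosomes, and tests it with \code{\link{fisher2x2}}. Overlaps within
#' each track are collapsed first.
#'
#' @param track_a,track_b \code{GRanges}.
#' @param chrom_sizes named numeric vector of chromosome lengths; every
#'   interval must fit inside its chromosome.
#' @return one-row data.frame from \code{\link{fisher2x2}} with the table
#'   counts and a \code{degenerate} flag (set when a margin is empty).
#' @export
intervalFisherBP <- function(track_a, track_b, chrom_sizes) {
    a <- GenomicRanges::reduce(track_a, ignore.strand = TRUE)
    b <- GenomicRanges::reduce(track_b, ignore.strand = TRUE)
    for (tr in list(a, b)) {
        chr <- as.character(GenomicRanges::seqnames(tr))
        if (!all(chr %in% names(chrom_sizes)))
            stop("chromosome(s) missing from chrom_sizes: ",
                 paste(setdiff(chr, names(chrom_sizes)), collapse = ", "))
        if (any(GenomicRanges::end(tr) > chrom_sizes[chr]))
            stop("interval beyond chromosome length")
    }
    both <- sum(GenomicRanges::width(GenomicRanges::intersect(
        a, b, ignore.strand = TRUE)))
    a_only <- sum(GenomicRanges::width(a)) - both
    b_only <- sum(GenomicRanges::width(b)) - both
    genome <- sum(chrom_sizes)
    neither <- genome - both - a_only - b_only
    res <- fisher2x2(both, a_only, b_only, neither)
    res$degenerate <- (both + a_only == 0) || (both + b_only == 0) ||
        (b_only + neither == 0) || (a_only + neither == 0)
    res
}
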