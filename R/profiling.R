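# Strain-level metagenomic profiling: strain-specific marker gene selection
# (cross-genome similarity, mobile-element and contig-end filters),
# perfect-match read counting on both strands, RPKM normalisation and
# mixture proportion estimation over a time series.

#' Select strain-specific marker genes
#'
#' Candidates are the gene families unique to each strain. A candidate is
#' rejected when (a) any other strain's genome contains a local alignment of
#' at least `l_min` bp at `id_min` identity to it (seeded by a shared
#' k-mer on either strand, confirmed by local alignment), (b) its annotation
#' matches a blacklist keyword (mobile elements), or (c) it lies within
#' `end_distance` bp of a contig end. Up to `max_markers` survivors are
#' kept per strain, longest first. The full audit trail (candidate ->
#' kept/rejected + reason) is returned.
#'
#' @param table a `gene_family_table`.
#' @param genomes named list of `genome_record` objects.
#' @param filters a [marker_filter_config()].
#' @param ani optional precomputed [ani_matrix()]; when two strains exceed
#'   `filters$ani_warn_threshold` a warning is raised (multi-mapping risk).
#' @return object of class `marker_gene_set`: list with `markers`
#'   (data.frame strain, gene_id, length, seq) and `audit` (data.frame
#'   strain, gene_id, length, status, reason).
#' @export
select_marker_genes <- function(table, genomes, filters = marker_filter_config(),
                                ani = NULL) {
  stopifnot(inherits(table, "gene_family_table"), length(genomes) >= 2L)
  strains <- vapply(genomes, `[[`, character(1), "strain")
  names(genomes) <- strains
  if (!is.null(ani)) {
    hi <- which(ani > filters$ani_warn_threshold & upper.tri(ani),
                arr.ind = TRUE)
    if (nrow(hi) > 0L) {
      warning(sprintf(
        "strain pairs above %.1f%% ANI (multi-mapping risk): %s",
        filters$ani_warn_threshold,
        paste(rownames(ani)[hi[, 1]], colnames(ani)[hi[, 2]],
              sep = "~", collapse = ", ")), call. = FALSE)
    }
  }
  part <- classify_families(table)
  m <- table$members
  audit <- list()
  markers <- list()
  for (st in sort(strains)) {
    uniq <- part$unique[vapply(part$unique, function(f)
      all(m$genome[m$family == f] == st), logical(1))]
    cand_ids <- m$gene_id[m$family %in% uniq & m$genome == st]
    if (length(cand_ids) == 0L) {
      warning(sprintf("strain %s has no unique-family candidates", st),
              call. = FALSE)
      next
    }
    g <- genomes[[st]]
    ginfo <- g$genes[match(cand_ids, g$genes$gene_id), , drop = FALSE]
    seqs <- gene_sequences(g, cand_ids)
    status <- rep("kept", length(cand_ids))
    reason <- rep("", length(cand_ids))
    # (b) annotation blacklist
    bl <- grepl(paste(filters$blacklist, collapse = "|"), ginfo$product,
                ignore.case = TRUE)
    status[bl] <- "rejected"; reason[bl] <- "blacklist"
    # (c) contig-end distance
    clen <- nchar(g$contigs[ginfo$contig])
    near_end <- (ginfo$start - 1L) < filters$end_distance |
      (clen - ginfo$end) < filters$end_distance
    hit <- near_end & status == "kept"
    status[hit] <- "rejected"; reason[hit] <- "contig_end"
    # (a) cross-genome similarity, only for survivors
    for (i in which(status == "kept")) {
      if (.has_cross_hit(seqs[[i]], genomes[setdiff(strains, st)], filters)) {
        status[i] <- "rejected"; reason[i] <- "cross_hit"
      }
    }
    keep_idx <- which(status == "kept")
    keep_idx <- keep_idx[order(-ginfo$length[keep_idx],
                               cand_ids[keep_idx])]
    if (length(keep_idx) > filters$max_markers) {
      drop_idx <- keep_idx[-seq_len(filters$max_markers)]
      status[drop_idx] <- "rejected"; reason[drop_idx] <- "max_markers"
      keep_idx <- keep_idx[seq_len(filters$max_markers)]
    }
    audit[[st]] <- data.frame(strain = st, gene_id = cand_ids,
                              length = ginfo$length, status = status,
                              reason = reason, stringsAsFactors = FALSE)
    if (length(keep_idx) > 0L) {
      markers[[st]] <- data.frame(strain = st, gene_id = cand_ids[keep_idx],
                                  length = ginfo$length[keep_idx],
                                  seq = unname(seqs[keep_idx]),
                                  stringsAsFactors = FALSE)
    } else {
      warning(sprintf("strain %s: no candidate survived marker filtering", st),
              call. = FALSE)
    }
  }
  structure(list(markers = do.call(rbind, c(markers, list(make.row.names = FALSE))),
                 audit = do.call(rbind, c(audit, list(make.row.names = FALSE)))),
            class = "marker_gene_set")
}

# TRUE when `gene` has a disqualifying similarity hit in any of `others`:
# a shared k-mer (either strand) extended by local alignment to >= l_min bp
# at >= id_min identity.
.has_cross_hit <- function(gene, others, filters) {
  k <- filters$k
  L <- nchar(gene)
  if (L < k) return(FALSE)
  starts <- seq.int(1L, L - k + 1L)
  kmers <- unique(substring(gene, starts, starts + k - 1L))
  kmers_rc <- unique(substring(.revcomp(gene), starts, starts + k - 1L))
  pd <- Biostrings::PDict(c(kmers, kmers_rc))
  sm <- Biostrings::nucleotideSubstitutionMatrix(2, -3)
  for (og in others) {
    for (ci in seq_along(og$contigs)) {
      contig <- og$contigs[[ci]]
      hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(contig))
      pos <- unlist(lapply(hits, IRanges::start), use.names = FALSE)
      if (length(pos) == 0L) next
      p <- min(pos)
      win <- substring(contig, max(1L, p - L - 50L),
                       min(nchar(contig), p + L + 50L))
      for (q in c(gene, .revcomp(gene))) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(q), Biostrings::DNAString(win),
          type = "local", substitutionMatrix = sm,
          gapOpening = 5, gapExtension = 2)
        pa <- as.character(Biostrings::pattern(aln))
        sa <- as.character(Biostrings::subject(aln))
        ncols <- nchar(pa)
        if (ncols >= filters$l_min) {
          x <- as.integer(charToRaw(pa)); y <- as.integer(charToRaw(sa))
          idty <- sum(x == y & x %in% .BASE_BYTES) / ncols
          if (idty >= filters$id_min) return(TRUE)
        }
      }
    }
  }
  FALSE
}

#' Count reads matching markers perfectly
#'
#' A read counts for a marker iff the entire read matches a contiguous
#' stretch of the marker exactly, on either strand (BBMap "perfect mode"
#' semantics). Reads matching markers of more than one strain are discarded
#' and tallied separately; a read matching several markers of one strain
#' counts for each of them.
#'
#' @param reads character vector of read sequences (or a `read_set`).
#' @param markers a `marker_gene_set`.
#' @return list with `counts` (data.frame strain, gene_id, length, reads),
#'   `total_mapped` (number of distinct strain-assigned reads),
#'   `n_ambiguous` (reads discarded for matching > 1 strain) and
#'   `n_reads` (library size).
#' @export
map_reads_perfect <- function(reads, markers) {
  stopifnot(inherits(markers, "marker_gene_set"))
  if (inherits(reads, "read_set")) reads <- reads$reads$seq
  reads <- as.character(reads)
  mk <- markers$markers
  n_mk <- nrow(mk)
  hit_count <- integer(n_mk)
  n_reads <- length(reads)
  total_mapped <- 0L
  n_ambiguous <- 0L
  if (n_reads > 0L) {
    widths <- unique(nchar(reads))
    for (w in widths) {
      ridx <- which(nchar(reads) == w)
      # enumerate all w-length substrings of every marker (both strands)
      sub_tab <- list()
      for (i in seq_len(n_mk)) {
        s <- mk$seq[i]
        if (nchar(s) < w) next
        st <- seq_len(nchar(s) - w + 1L)
        subs <- unique(c(substring(s, st, st + w - 1L),
                         substring(.revcomp(s), st, st + w - 1L)))
        sub_tab[[length(sub_tab) + 1L]] <-
          data.frame(seq = subs, marker = i, stringsAsFactors = FALSE)
      }
      if (length(sub_tab) == 0L) next
      sub_df <- do.call(rbind, sub_tab)
      # map each read to the set of markers containing it as a substring
      key <- unique(sub_df$seq)
      by_key <- split(sub_df$marker, factor(sub_df$seq, levels = key))
      ridx_hit <- match(reads[ridx], key)
      hit_rows <- which(!is.na(ridx_hit))
      if (length(hit_rows) == 0L) next
      mk_sets <- by_key[ridx_hit[hit_rows]]
      strain_sets <- lapply(mk_sets, function(ms) unique(mk$strain[ms]))
      ambiguous <- lengths(strain_sets) > 1L
      n_ambiguous <- n_ambiguous + sum(ambiguous)
      ok <- which(!ambiguous)
      total_mapped <- total_mapped + length(ok)
      if (length(ok) > 0L) {
        tab <- table(unlist(mk_sets[ok], use.names = FALSE))
        ids <- as.integer(names(tab))
        hit_count[ids] <- hit_count[ids] + as.integer(tab)
      }
    }
  }
  list(counts = data.frame(strain = mk$strain, gene_id = mk$gene_id,
                           length = mk$length, reads = hit_count,
                           stringsAsFactors = FALSE),
       total_mapped = total_mapped, n_ambiguous = n_ambiguous,
       n_reads = n_reads)
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM = (1e9 * reads mapped to the gene) / (total mapped reads * gene
#' length in bp).
#'
#' @param mapped_reads reads mapped to the gene.
#' @param gene_length gene length in bp (> 0).
#' @param total_mapped_reads total mapped reads in the library.
#' @return RPKM value (0 with a warning when nothing mapped).
#' @export
rpkm <- function(mapped_reads, gene_length, total_mapped_reads) {
  if (any(gene_length <= 0)) stop("gene_length must be > 0", call. = FALSE)
  if (any(total_mapped_reads < mapped_reads)) {
    stop("total_mapped_reads must be >= mapped_reads", call. = FALSE)
  }
  if (any(total_mapped_reads == 0)) {
    warning("total_mapped_reads is 0; RPKM reported as 0", call. = FALSE)
    return(ifelse(total_mapped_reads == 0, 0,
                  1e9 * mapped_reads / (total_mapped_reads * gene_length)))
  }
  1e9 * mapped_reads / (total_mapped_reads * gene_length)
}

#' Strain abundance profile over a time series
#'
#' Maps each time point's reads on the marker set, computes per-marker RPKM
#' (library size = strain-assigned mapped reads of that time point), and
#' summarises per strain by the mean (or median) RPKM over its markers.
#' Strain proportions are the per-strain summaries normalised to sum to 1
#' within each time point.
#'
#' @param read_sets named list (time point -> reads: character vector or
#'   `read_set`).
#' @param markers a `marker_gene_set`.
#' @param aggregate `"mean"` (default) or `"median"` RPKM across markers.
#' @return object of class `abundance_profile`: list with `profile`
#'   (data.frame time, strain, mapped_reads, rpkm, proportion), `library`
#'   (data.frame time, n_reads, total_mapped, n_ambiguous).
#' @export
profile_timeseries <- function(read_sets, markers,
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(markers, "marker_gene_set"), length(read_sets) >= 1L)
  agg <- if (aggregate == "mean") mean else median
  strains <- sort(unique(markers$markers$strain))
  prof <- list()
  lib <- list()
  for (tp in names(read_sets)) {
    res <- map_reads_perfect(read_sets[[tp]], markers)
    cnt <- res$counts
    cnt$rpkm <- rpkm(cnt$reads, cnt$length,
                     max(res$total_mapped, 1L)) *
      (res$total_mapped > 0L)
    strain_rpkm <- vapply(strains, function(st)
      agg(cnt$rpkm[cnt$strain == st]), numeric(1))
    strain_reads <- vapply(strains, function(st)
      sum(cnt$reads[cnt$strain == st]), numeric(1))
    tot <- sum(strain_rpkm)
    prop <- if (res$total_mapped > 0L && tot > 0) strain_rpkm / tot
    else rep(NA_real_, length(strains))
    prof[[tp]] <- data.frame(time = tp, strain = strains,
                             mapped_reads = strain_reads,
                             rpkm = unname(strain_rpkm),
                             proportion = unname(prop),
                             stringsAsFactors = FALSE)
    lib[[tp]] <- data.frame(time = tp, n_reads = res$n_reads,
                            total_mapped = res$total_mapped,
                            n_ambiguous = res$n_ambiguous,
                            stringsAsFactors = FALSE)
  }
  structure(list(profile = do.call(rbind, c(prof, list(make.row.names = FALSE))),
                 library = do.call(rbind, c(lib, list(make.row.names = FALSE)))),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("<abundance_profile>\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}
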