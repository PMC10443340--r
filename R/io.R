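# File interchange: FASTA + GFF3 per strain, FASTQ for reads, TSV truth
# tables and a JSON run manifest. Sequence I/O goes through Biostrings and
# GFF3 through rtracklayer/GenomicRanges.

#' Write a genome record as FASTA and GFF3
#'
#' One FASTA of contigs and one GFF3 of gene features per strain; the GFF3
#' `ID` attribute is the gene ID and `product` carries the annotation label.
#' The rtracklayer `##date` header line is stripped so that re-running a
#' simulation yields byte-identical files.
#'
#' @param genome a `genome_record`.
#' @param dir output directory.
#' @return invisibly, the two file paths written.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "genome_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(genome$strain, ".fna"))
  gff <- file.path(dir, paste0(genome$strain, ".gff3"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), fa, width = 80L)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    type = "gene",
    ID = g$gene_id,
    product = g$product)
  rtracklayer::export.gff3(gr, gff)
  lines <- readLines(gff)
  writeLines(lines[!startsWith(lines, "##date")], gff)
  invisible(c(fasta = fa, gff3 = gff))
}

#' Read a genome record from FASTA and GFF3
#'
#' @param fasta path to the contig FASTA.
#' @param gff3 path to the gene GFF3 (features of type `gene`, `ID`
#'   attribute = gene ID).
#' @param strain strain label; default: FASTA file name without extension.
#' @return a `genome_record`.
#' @export
read_genome <- function(fasta, gff3, strain = NULL) {
  if (is.null(strain)) {
    strain <- sub("\\.(fa|fna|fasta)$", "", basename(fasta))
  }
  contigs <- Biostrings::readDNAStringSet(fasta)
  contig_names <- sub("\\s.*$", "", names(contigs))
  contigs <- setNames(as.character(contigs), contig_names)
  gr <- rtracklayer::import(gff3)
  gr <- gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = gr$ID,
    family = NA_character_,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr),
    product = if (!is.null(gr$product)) gr$product else NA_character_,
    stringsAsFactors = FALSE)
  structure(list(strain = strain, contigs = contigs, genes = genes),
            class = "genome_record")
}

#' Write simulated reads as FASTQ
#'
#' Constant PHRED quality (default 35, "D"); qualities are carried for
#' format compliance but not used by the perfect-match profiler.
#'
#' @param read_set a `read_set` from [simulate_reads()].
#' @param path output FASTQ path (".gz" suffix compresses).
#' @param quality_char constant quality character.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(read_set, path, quality_char = "D") {
  stopifnot(inherits(read_set, "read_set"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  r <- read_set$reads
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  qual <- strrep(quality_char, nchar(r$seq))
  writeLines(paste0("@", r$read_id, " strain=", r$strain, "\n", r$seq,
                    "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file as a character vector of sequences
#'
#' @param path FASTQ path (optionally gzipped).
#' @return named character vector (names = read IDs).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write simulation truth tables
#'
#' Emits TSVs for family membership, rate classes and variant positions,
#' the true tree as Newick, and a JSON manifest echoing the configuration.
#'
#' @param sim result of [simulate_pangenome()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- sim$truth
  .write_tsv(truth$gene_family_truth, file.path(dir, "gene_family_truth.tsv"))
  .write_tsv(truth$per_gene_rate_class,
             file.path(dir, "per_gene_rate_class.tsv"))
  vs <- truth$true_variant_sites
  vdf <- data.frame(
    family = rep(names(vs), lengths(vs)),
    position0 = unlist(vs, use.names = FALSE),
    stringsAsFactors = FALSE)
  .write_tsv(vdf, file.path(dir, "true_variant_sites.tsv"))
  if (!is.null(truth$true_tree)) {
    ape::write.tree(truth$true_tree, file.path(dir, "true_tree.nwk"))
  }
  cfg <- sim$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
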