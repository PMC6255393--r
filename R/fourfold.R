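#' Fourfold-degenerate coding sites
#'
#' Identifies genomic positions at which all four bases encode the same amino
#' acid, given the annotated reading frame of the primary transcript. This is
#' computed directly from the codon table: for each coding position the codon
#' is translated with each of the four bases substituted, and the position is
#' reported when the four translations agree (in practice only third codon
#' positions qualify). Equivalent to building four pseudo-genomes, one per
#' base, and comparing their translations.
#'
#' The primary transcript of each gene is taken to be the one with the longest
#' total CDS (ties broken by transcript id). Transcripts whose CDS length is
#' not a multiple of three after the annotated phase is trimmed are skipped
#' with a warning.
#'
#' @param annotation GFF3 file with CDS features carrying `Parent` attributes
#'   (and optionally gene-level grouping), or a data.frame as returned by
#'   internal parsing with columns chrom, start, end, strand, phase,
#'   transcript, gene.
#' @param reference FASTA file of the reference genome, or a named character
#'   vector of sequences.
#' @return data.frame(chrom, pos) of fourfold-degenerate positions (1-based).
#' @export
fourfold_sites <- function(annotation, reference) {
  cds <- if (is.data.frame(annotation)) annotation else read_cds_gff3(annotation)
  seqs <- if (is.character(reference) && file.exists(reference[1]) && length(reference) == 1) {
    x <- Biostrings::readDNAStringSet(reference)
    names(x) <- sub("\\s.*", "", names(x))
    x
  } else Biostrings::DNAStringSet(reference)

  # choose primary transcript per gene: longest total CDS, ties by id
  len <- tapply(cds$end - cds$start + 1L, cds$transcript, sum)
  tr_gene <- tapply(cds$gene, cds$transcript, `[`, 1)
  ord <- order(tr_gene, -as.numeric(len[names(tr_gene)]), names(tr_gene))
  primary <- names(tr_gene)[ord][!duplicated(tr_gene[ord])]
  cds <- cds[cds$transcript %in% primary, , drop = FALSE]

  out <- list(); k <- 0
  gc <- Biostrings::GENETIC_CODE
  for (tr in unique(cds$transcript)) {
    ex <- cds[cds$transcript == tr, , drop = FALSE]
    minus <- ex$strand[1] == "-"
    ex <- ex[order(ex$start, decreasing = minus), , drop = FALSE]
    # genomic coordinates of coding positions, 5'->3'
    pos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
      p <- ex$start[i]:ex$end[i]
      if (minus) rev(p) else p
    }))
    phase <- suppressWarnings(as.integer(ex$phase[1]))
    if (is.na(phase)) phase <- 0L
    if (phase > 0) pos <- pos[-seq_len(phase)]
    if (length(pos) %% 3 != 0) {
      warning("CDS length of ", tr, " not a multiple of 3; transcript skipped")
      next
    }
    chrom <- ex$chrom[1]
    s <- as.character(Biostrings::subseq(seqs[[chrom]], 1, length(seqs[[chrom]])))
    bases <- strsplit(s, "")[[1]][pos]
    if (minus) bases <- c(A = "T", C = "G", G = "C", T = "A")[bases]
    ncod <- length(pos) %/% 3
    codons <- matrix(bases, nrow = 3)
    third_ff <- logical(ncod)
    # degeneracy of the third position: prefix invariant
    pre <- paste0(codons[1, ], codons[2, ])
    for (p2 in unique(pre)) {
      aa <- gc[paste0(p2, c("A", "C", "G", "T"))]
      if (length(unique(aa)) == 1) third_ff[pre == p2] <- TRUE
    }
    # first and second codon positions are never fourfold degenerate in the
    # standard code; only third positions are reported
    gpos <- pos[seq(3, length(pos), by = 3)][third_ff]
    if (length(gpos) > 0) {
      k <- k + 1
      out[[k]] <- data.frame(chrom = chrom, pos = gpos, stringsAsFactors = FALSE)
    }
  }
  if (k == 0) return(data.frame(chrom = character(), pos = integer()))
  res <- unique(do.call(rbind, out))
  res[order(res$chrom, res$pos), , drop = FALSE]
}

#' Read CDS features from a GFF3 file
#'
#' @param path GFF3 file
#' @return data.frame(chrom, start, end, strand, phase, transcript, gene)
#'   with 1-based inclusive coordinates.
#' @export
read_cds_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  parent <- as.character(S4Vectors::unlist(cds$Parent))
  gene <- if (!is.null(cds$gene_id)) as.character(cds$gene_id) else sub("\\..*$", "", parent)
  data.frame(chrom = as.character(GenomicRanges::seqnames(cds)),
             start = GenomicRanges::start(cds), end = GenomicRanges::end(cds),
             strand = as.character(GenomicRanges::strand(cds)),
             phase = as.integer(cds$phase), transcript = parent, gene = gene,
             stringsAsFactors = FALSE)
}
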