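#' Construct a gene panel
#'
#' A panel maps gene symbols to a genomic span and a set of exon
#' intervals; it drives both the gene filter (full gene body, introns
#' included) and region classification (exon vs near-splice vs
#' deep-intronic). Intervals are held 1-based inclusive internally and
#' converted to/from BED's 0-based half-open convention at the file
#' boundary. Overlapping exon intervals of a gene are merged.
#'
#' @param exons Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `gene`.
#' @param spans Optional data frame with the same columns giving the
#'   gene spans; defaults to the hull of each gene's exons.
#' @param name Panel name.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(exons, spans = NULL, name = "panel") {
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(exons)))
  if (nrow(exons) == 0) stop("gene panel must contain at least one exon interval")
  if (any(exons$end < exons$start)) stop("exon interval with end < start")
  gr <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start, exons$end),
                               gene = exons$gene)
  merged <- lapply(split(gr, gr$gene), function(g) {
    red <- GenomicRanges::reduce(g)
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(red)),
               start = GenomicRanges::start(red),
               end = GenomicRanges::end(red),
               gene = g$gene[1], stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, merged)
  exons <- exons[order(exons$gene, exons$chrom, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (is.null(spans)) {
    spans <- do.call(rbind, lapply(split(exons, exons$gene), function(e) {
      data.frame(chrom = e$chrom[1], start = min(e$start), end = max(e$end),
                 gene = e$gene[1], stringsAsFactors = FALSE)
    }))
  } else {
    spans <- as.data.frame(spans, stringsAsFactors = FALSE)
    if (any(spans$end < spans$start)) stop("gene span with end < start")
  }
  rownames(spans) <- NULL
  bad <- vapply(seq_len(nrow(exons)), function(i) {
    s <- spans[spans$gene == exons$gene[i] & spans$chrom == exons$chrom[i], ]
    !nrow(s) || !any(exons$start[i] >= s$start & exons$end[i] <= s$end)
  }, TRUE)
  if (any(bad)) stop("exon interval outside its gene span: ", exons$gene[bad][1])
  structure(list(exons = exons, spans = spans, name = name),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel '%s': %d gene(s), %d exon interval(s)\n",
              x$name, length(panel_genes(x)), nrow(x$exons)))
  invisible(x)
}

#' Gene symbols in a panel
#' @param panel A [gene_panel()].
#' @return Character vector of gene symbols.
#' @export
panel_genes <- function(panel) unique(panel$spans$gene)

#' Read a gene panel from a BED file
#'
#' Expects 4+ column BED (chrom, start, end, name) in the usual 0-based
#' half-open convention. Each line is an exon interval of the named
#' gene; a line whose name carries the suffix `:span` instead declares
#' the gene's span explicitly (otherwise the span is the hull of the
#' gene's exons).
#'
#' @param path Path to a BED file.
#' @param name Panel name; defaults to the file name.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path, name = NULL) {
  if (!file.exists(path)) stop("panel BED not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) stop("panel BED needs a 4th (gene name) column")
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   gene = gr$name, stringsAsFactors = FALSE)
  if (any(df$end < df$start)) stop("interval with end <= start in panel BED")
  is_span <- grepl(":span$", df$gene)
  spans <- NULL
  if (any(is_span)) {
    spans <- df[is_span, , drop = FALSE]
    spans$gene <- sub(":span$", "", spans$gene)
  }
  exons <- df[!is_span, , drop = FALSE]
  if (!nrow(exons)) stop("panel BED contains no exon intervals")
  gene_panel(exons, spans = spans,
             name = if (is.null(name)) basename(path) else name)
}

#' Write a gene panel as a BED file
#'
#' Inverse of [read_gene_panel()]: exon lines named by gene, plus
#' explicit `<gene>:span` lines.
#'
#' @param panel A [gene_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_panel <- function(panel, path) {
  spans <- panel$spans
  spans$gene <- paste0(spans$gene, ":span")
  df <- rbind(panel$exons, spans)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               name = df$gene)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

## Index of the panel span containing chrom:pos (first match, preferring
## a span whose gene equals `gene` when given); NA when outside all spans.
span_hit <- function(panel, chrom, pos, gene = NULL) {
  hits <- which(panel$spans$chrom == chrom &
                panel$spans$start <= pos & panel$spans$end >= pos)
  if (!length(hits)) return(NA_integer_)
  if (!is.null(gene) && nzchar(gene)) {
    pref <- hits[panel$spans$gene[hits] == gene]
    if (length(pref)) return(pref[1])
  }
  hits[1]
}
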