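## Annotation file IO. Standard formats go through rtracklayer; the TSV
## report reproduces the column layout of the published comparison tables.

.role_from_gff_type <- function(type) {
  map <- c(five_prime_UTR = "five_prime_utr",
           three_prime_UTR = "three_prime_utr",
           exon = "exon", intron = "intron", CDS = "body")
  unname(map[as.character(type)])
}

.gff_type_from_role <- c(five_prime_utr = "five_prime_UTR",
                         three_prime_utr = "three_prime_UTR",
                         exon = "exon", intron = "intron", body = "CDS")

#' Read gene models from GFF3, GTF or BED12
#'
#' Parsing of the standard formats is delegated to
#' [rtracklayer::import()]; features are grouped by transcript and mapped to
#' role-typed [gene_model()] segments. BED12 blocks become exons (coordinates
#' converted from 0-based half-open through the centralized
#' [from_bed_coords()] pair).
#'
#' @param path input file.
#' @param format one of `"GFF3"`, `"GTF"`, `"BED12"`; guessed from the file
#'   extension when missing.
#' @return A named list of `gene_model` objects.
#' @export
read_annotations <- function(path, format = c("auto", "GFF3", "GTF", "BED12")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff3 = , gff = "GFF3", gtf = "GTF", bed = "BED12",
                     stop("cannot guess annotation format from '", ext, "'"))
  }
  if (format == "BED12") {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e)))
    models <- lapply(seq_along(gr), function(i) {
      x <- gr[i]
      nm <- if (!is.null(x$name) && !is.na(x$name)) x$name else paste0("bed_", i)
      blocks <- if (!is.null(x$blocks)) x$blocks[[1]] else
        IRanges::IRanges(1, GenomicRanges::width(x))
      abs_start <- GenomicRanges::start(x) + IRanges::start(blocks) - 1
      abs_end <- GenomicRanges::start(x) + IRanges::end(blocks) - 1
      seg <- data.frame(role = "exon",
                        chrom = as.character(GenomicRanges::seqnames(x)),
                        start = abs_start, end = abs_end,
                        strand = as.character(GenomicRanges::strand(x)),
                        stringsAsFactors = FALSE)
      seg$strand[seg$strand == "*"] <- "*"
      gene_model(nm, seg)
    })
    names(models) <- vapply(models, `[[`, "", "gene_id")
    return(models)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "GFF3") "gff3" else "gtf"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  df <- as.data.frame(gr)
  df$role <- .role_from_gff_type(df$type)
  feat <- df[!is.na(df$role), , drop = FALSE]
  if (!nrow(feat)) stop("no UTR/exon/intron/CDS features in ", path)
  txid <- if ("transcript_id" %in% names(feat) &&
              any(!is.na(feat$transcript_id))) {
    feat$transcript_id
  } else if ("Parent" %in% names(feat)) {
    vapply(feat$Parent, function(p) if (length(p)) as.character(p[[1]])
           else NA_character_, "")
  } else feat$ID
  txid[is.na(txid)] <- "unassigned"
  by_tx <- split(feat, txid)
  models <- lapply(names(by_tx), function(tid) {
    rows <- by_tx[[tid]]
    gid <- if ("gene_id" %in% names(rows) && any(!is.na(rows$gene_id))) {
      rows$gene_id[!is.na(rows$gene_id)][1]
    } else tid
    seg <- data.frame(role = rows$role, chrom = as.character(rows$seqnames),
                      start = rows$start, end = rows$end,
                      strand = as.character(rows$strand),
                      stringsAsFactors = FALSE)
    gene_model(gid, seg, transcript_id = tid)
  })
  names(models) <- names(by_tx)
  models
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write annotations or re-annotation records
#'
#' `format = "GFF3"` writes role-typed features (one mRNA per gene model or
#' per alternative of a re-annotation record). `format = "TSV-table"`
#' reproduces the published comparison-table layout: annotation label,
#' chromosome, start, end, strand, coverage (bp), with minus-strand rows
#' printed in their original high-to-low display order.
#'
#' @param records a list of `gene_model` and/or `reannotation_record`
#'   objects.
#' @param path output file.
#' @param format `"GFF3"` or `"TSV-table"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path, format = c("GFF3", "TSV-table")) {
  format <- match.arg(format)
  if (inherits(records, c("gene_model", "reannotation_record"))) {
    records <- list(records)
  }
  if (format == "TSV-table") {
    rows <- list()
    for (rec in records) {
      if (inherits(rec, "gene_model")) {
        seg <- rec$segments
        for (i in seq_len(nrow(seg))) {
          co <- if (seg$display_rev[i]) c(seg$end[i], seg$start[i]) else
            c(seg$start[i], seg$end[i])
          rows[[length(rows) + 1]] <- data.frame(
            annotation = paste0(rec$gene_id, ": ", seg$role[i]),
            chr = seg$chrom[i], start = co[1], end = co[2],
            strand = seg$strand[i], coverage_bp = seg$end[i] - seg$start[i])
        }
      } else if (inherits(rec, "reannotation_record")) {
        seg <- rec$segments
        for (i in seq_len(nrow(seg))) {
          lab <- if (!is.na(rec$evidence[i])) {
            paste0(rec$evidence[i], ": ", seg$role[i])
          } else paste0("proposed: ", seg$role[i])
          rows[[length(rows) + 1]] <- data.frame(
            annotation = lab, chr = seg$chrom[i],
            start = seg$start[i], end = seg$end[i], strand = seg$strand[i],
            coverage_bp = rec$segment_lengths[i])
        }
        si <- rec$summary_interval
        sm <- if (any(seg$display_rev)) c(si$end, si$start) else
          c(si$start, si$end)
        rows[[length(rows) + 1]] <- data.frame(
          annotation = "Summary", chr = si$chrom, start = sm[1], end = sm[2],
          strand = si$strand, coverage_bp = rec$summary_length_bp)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(path))
  }
  ## GFF3
  lines <- c("##gff-version 3")
  esc <- function(x) gsub("[;=]", "_", x)
  for (rec in records) {
    models <- if (inherits(rec, "reannotation_record")) {
      if (length(rec$alternatives)) rec$alternatives else
        list(gene_model(rec$gene_id,
                        rec$segments[, c("role", "chrom", "start", "end",
                                         "strand")],
                        source = "proposed"))
    } else list(rec)
    for (k in seq_along(models)) {
      gm <- models[[k]]
      seg <- gm$segments
      tid <- if (length(models) > 1) paste0(gm$transcript_id, ".", k) else
        gm$transcript_id
      lines <- c(lines, paste(
        gm$chrom, "threeprime", "mRNA", min(seg$start), max(seg$end), ".",
        gm$strand, ".",
        sprintf("ID=%s;Parent=%s", esc(tid), esc(gm$gene_id)), sep = "\t"))
      for (i in order(seg$start)) {
        lines <- c(lines, paste(
          seg$chrom[i], "threeprime", .gff_type_from_role[[seg$role[i]]],
          seg$start[i], seg$end[i], ".", seg$strand[i], ".",
          sprintf("Parent=%s", esc(tid)), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
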