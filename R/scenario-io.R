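## Scenario serialization: the generator's outputs in the same standard
## formats the pipeline consumes (FASTA/GFF3/bedGraph/BED/BED12 + JSON
## truth), and the reader that reconstructs a scenario from a directory.

.write_bedgraph_cv <- function(cv, path) {
  r <- rle(cv$depth)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%g", cv$chrom,
                   cv$start + starts[keep] - 2,   # bed 0-based start
                   cv$start + ends[keep] - 1, r$values[keep])
  writeLines(lines, path)
  invisible(path)
}

.read_bedgraph_cv <- function(path, source = "RNA-seq") {
  if (!file.size(path)) stop("empty bedGraph: ", path)
  df <- utils::read.table(path, sep = "\t", col.names = c("chrom", "start0",
                                                          "end", "value"))
  start1 <- min(df$start0) + 1
  len <- max(df$end) - start1 + 1
  depth <- numeric(len)
  for (i in seq_len(nrow(df))) {
    co <- from_bed_coords(df$start0[i], df$end[i])
    depth[(co$start - start1 + 1):(co$end - start1 + 1)] <- df$value[i]
  }
  coverage_vector(df$chrom[1], start1, depth, source = source)
}

.write_track_bedgraph <- function(track, dir, rep_id) {
  for (st in c("+", "-")) {
    sub <- track[track$strand == st, , drop = FALSE]
    path <- file.path(dir, sprintf("drs_%s_%s.bedGraph", rep_id,
                                   if (st == "+") "plus" else "minus"))
    lines <- sprintf("%s\t%d\t%d\t%g", sub$chrom, sub$pos - 1, sub$pos,
                     sub$count)
    writeLines(lines, path)
  }
}

.read_track_bedgraph <- function(dir, rep_id) {
  rows <- list()
  for (st in c("+", "-")) {
    path <- file.path(dir, sprintf("drs_%s_%s.bedGraph", rep_id,
                                   if (st == "+") "plus" else "minus"))
    if (!file.exists(path) || !file.size(path)) next
    df <- utils::read.table(path, sep = "\t",
                            col.names = c("chrom", "start0", "end", "value"))
    rows[[length(rows) + 1]] <- data.frame(chrom = df$chrom,
                                           pos = df$start0 + 1, strand = st,
                                           count = df$value,
                                           stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(three_prime_track(data.frame(chrom = character(0),
                                        pos = numeric(0),
                                        strand = character(0),
                                        count = numeric(0)), rep_id))
  }
  tr <- do.call(rbind, rows)
  tr <- tr[order(tr$chrom, tr$strand, tr$pos), , drop = FALSE]
  rownames(tr) <- NULL
  three_prime_track(tr, rep_id)
}

#' Write a scenario to a directory of standard-format files
#'
#' Emits `genome.fa`, `annotation.gff3`, per-replicate stranded 3'-end
#' bedGraph tracks, `rnaseq.bedGraph`, `junctions.bed` (score = spanning
#' reads), `est.bed` (BED12, strand flag as generated), `srna.bedGraph`
#' when present, and `truth.json`. Output is deterministic: identical
#' scenarios produce byte-identical files.
#'
#' @param scn a [generate_scenario()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(scn$genome, file.path(dir, "genome.fa"),
                              width = 70)
  genes <- if (!is.null(scn$genes)) scn$genes else list(scn$gene)
  write_annotations(genes, file.path(dir, "annotation.gff3"), "GFF3")
  for (tr in scn$drs_tracks) {
    .write_track_bedgraph(tr, dir, attr(tr, "replicate_id"))
  }
  .write_bedgraph_cv(scn$rnaseq, file.path(dir, "rnaseq.bedGraph"))
  if (!is.null(scn$junctions) && nrow(scn$junctions)) {
    jx <- scn$junctions
    lines <- sprintf("%s\t%d\t%d\tjunction_%03d\t%d\t+", jx$chrom,
                     jx$donor - 1, jx$acceptor, seq_len(nrow(jx)), jx$count)
    writeLines(lines, file.path(dir, "junctions.bed"))
  }
  if (!is.null(scn$est) && nrow(scn$est)) {
    e <- scn$est
    bs <- e$start - 1
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d\t0",
                     e$chrom, bs, e$end, e$name, e$strand, bs, e$end,
                     e$end - bs)
    writeLines(lines, file.path(dir, "est.bed"))
  }
  if (!is.null(scn$srna)) {
    .write_bedgraph_cv(scn$srna, file.path(dir, "srna.bedGraph"))
  }
  truth <- scn$truth
  truth$scenario <- scn$spec$scenario
  truth$seed <- scn$spec$seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a scenario directory back into memory
#'
#' Inverse of [write_scenario()] for pipeline use: coordinates round-trip
#' exactly.
#'
#' @param dir a directory written by [write_scenario()].
#' @return a list with the same track/annotation structure as a generated
#'   scenario (the truth record is attached when `truth.json` is present).
#' @export
read_scenario <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  genes <- read_annotations(file.path(dir, "annotation.gff3"), "GFF3")
  rep_files <- list.files(dir, pattern = "^drs_.*_plus\\.bedGraph$")
  rep_ids <- sort(unique(sub("^drs_(.*)_plus\\.bedGraph$", "\\1", rep_files)))
  tracks <- lapply(rep_ids, function(id) .read_track_bedgraph(dir, id))
  rnaseq <- .read_bedgraph_cv(file.path(dir, "rnaseq.bedGraph"), "RNA-seq")
  jx_path <- file.path(dir, "junctions.bed")
  junctions <- if (file.exists(jx_path) && file.size(jx_path)) {
    df <- utils::read.table(jx_path, sep = "\t")
    data.frame(chrom = df$V1, donor = df$V2 + 1, acceptor = df$V3,
               count = df$V5, stringsAsFactors = FALSE)
  } else NULL
  est_path <- file.path(dir, "est.bed")
  est <- if (file.exists(est_path) && file.size(est_path)) {
    df <- utils::read.table(est_path, sep = "\t")
    data.frame(chrom = df$V1, start = df$V2 + 1, end = df$V3,
               strand = df$V6, name = df$V4, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), name = character(0))
  }
  srna_path <- file.path(dir, "srna.bedGraph")
  srna <- if (file.exists(srna_path) && file.size(srna_path)) {
    .read_bedgraph_cv(srna_path, "sRNA")
  } else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  structure(list(genome = genome, gene = genes[[1]], genes = genes,
                 drs_tracks = tracks, rnaseq = rnaseq, junctions = junctions,
                 est = est, srna = srna, truth = truth, spec = NULL),
            class = "scenario")
}

#' Emit the full fixture suite
#'
#' Writes one directory per scenario plus a manifest with seeds and file
#' checksums, so the suite is reproducible and self-describing.
#'
#' @param out_dir output directory.
#' @param base_seed integer; scenario `i` uses `base_seed + i - 1`.
#' @return the manifest (a list), invisibly.
#' @export
emit_fixture_suite <- function(out_dir, base_seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (i in seq_along(.SCENARIOS)) {
    sc <- .SCENARIOS[i]
    seed <- base_seed + i - 1L
    scn <- generate_scenario(sc, seed = seed)
    d <- file.path(out_dir, sc)
    write_scenario(scn, d)
    files <- sort(list.files(d))
    manifest[[sc]] <- list(
      seed = seed,
      expected_endpoint = scn$truth$expected_endpoint %||% NA,
      files = as.list(stats::setNames(
        unname(tools::md5sum(file.path(d, files))), files)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
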