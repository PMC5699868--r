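# Readers and writers for the plain-text formats the pipeline consumes and
# produces: FASTA, spot-table CSV, titration CSV, Sparky-style peak lists,
# cross-link CSV, SASA CSV and enrichment/restraint TSVs.

#' Write protein sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, as.string = TRUE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(s, as.character, character(1))), names(s))
}

#' Write / read a peptide-array spot table
#'
#' CSV with columns `spot_id`, `protein_id`, `start_1based`, `sequence`,
#' `replicate`, `intensity`.
#'
#' @param table spot table `data.frame`.
#' @param path file path.
#' @return the table (read) or `path` invisibly (write).
#' @export
write_spot_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @export
read_spot_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "protein_id", "start_1based", "sequence",
            "replicate", "intensity")
  stopifnot(all(need %in% names(tab)))
  tab
}

#' Write / read a titration table
#'
#' CSV with columns `conc_uM` and `response`; read back as the
#' log10-concentration form used by [fit_binding()].
#'
#' @param data titration `data.frame` with `x` (log10 micromolar) and
#'   `response`.
#' @param path file path.
#' @return the data (read) or `path` invisibly (write).
#' @export
write_titration_csv <- function(data, path) {
  utils::write.csv(data.frame(conc_uM = 10^data$x,
                              response = data$response),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("conc_uM", "response") %in% names(tab)),
            all(tab$conc_uM > 0))
  data.frame(x = log10(tab$conc_uM), response = tab$response)
}

#' Write / read a Sparky-style peak list
#'
#' Whitespace-separated text, one peak per line:
#' `label  w1_ppm  w2_ppm  height`, with w1 the 13C and w2 the 1H
#' dimension.  Lines starting with `#` and an optional `Assignment` header
#' line are skipped on read.
#'
#' @param peaks peak list `data.frame` (columns `label`, `w_C`, `w_H`,
#'   `height`).
#' @param path file path.
#' @return the peak list (read) or `path` invisibly (write).
#' @export
write_sparky <- function(peaks, path) {
  writeLines(c("# label  w1_ppm(13C)  w2_ppm(1H)  height",
               sprintf("%-12s %10.4f %10.4f %14.6g",
                       peaks$label, peaks$w_C, peaks$w_H, peaks$height)),
             path)
  invisible(path)
}

#' @rdname write_sparky
#' @export
read_sparky <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines <- lines[!grepl("^\\s*Assignment", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  stopifnot(all(lengths(parts) >= 4))
  data.frame(
    label = vapply(parts, `[`, character(1), 1),
    w_C = as.numeric(vapply(parts, `[`, character(1), 2)),
    w_H = as.numeric(vapply(parts, `[`, character(1), 3)),
    height = as.numeric(vapply(parts, `[`, character(1), 4)))
}

#' Write / read a cross-link quantification table
#'
#' CSV with columns `lys_a`, `lys_b`, `band`, `condition`, `mean_pct`,
#' `sd_pct` (long format; band 1 is the monomer band).
#'
#' @param table cross-link `data.frame`.
#' @param path file path.
#' @return the table (read) or `path` invisibly (write).
#' @export
write_xlink_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xlink_csv
#' @export
read_xlink_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lys_a", "lys_b", "band", "mean_pct") %in% names(tab)))
  tab
}

#' Write a per-residue SASA table
#'
#' CSV with columns `chain`, `resno`, `resname`, `sasa_A2`.
#'
#' @param residue_sasa the `residue` element of a [sasa()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sasa_csv <- function(residue_sasa, path) {
  out <- residue_sasa
  names(out)[names(out) == "sasa"] <- "sasa_A2"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an enrichment result as TSV
#'
#' Columns `aa`, `log2_enrichment`, `sd`, `p`, `flag`.
#'
#' @param result an [aa_enrichment()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(result, path) {
  out <- data.frame(aa = result$aa, log2_enrichment = result$log2_enrichment,
                    sd = result$sd, p = result$p_value, flag = result$flag)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the top-binder spots as a BED-like TSV
#'
#' Half-open 0-based intervals: `protein_id`, `start`, `end`, `spot_id`,
#' `score` (mean normalized intensity).
#'
#' @param table normalized spot table.
#' @param top_set spot ids from [select_top()].
#' @param design an [array_design()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_topset_tsv <- function(table, top_set, design, path) {
  agg <- stats::aggregate(intensity ~ spot_id + protein_id + start_1based,
                          data = table, FUN = mean)
  agg <- agg[agg$spot_id %in% top_set, ]
  agg <- agg[order(agg$protein_id, agg$start_1based), ]
  out <- data.frame(protein_id = agg$protein_id,
                    start = agg$start_1based - 1L,
                    end = agg$start_1based - 1L + design$tile_length,
                    spot_id = agg$spot_id, score = agg$intensity)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
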