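# Plain-text interchange formats: wide twin-pair CSV with a JSON sidecar of
# generating parameters, tab-separated dosage panels, 3-column weight
# tables, and the GCTA text GRM convention (gzipped triplets + id file).

#' Write / read a twin-pair table as wide CSV
#'
#' One row per pair. If the table carries simulation metadata (`sim_meta`
#' attribute), a JSON sidecar `<path>.json` records the generator, seed and
#' parameters.
#'
#' @param data A `twin_pairs` data frame.
#' @param path CSV file path.
#' @return `write_twin_pairs` returns `path` invisibly; `read_twin_pairs`
#'   returns a `twin_pairs` data frame (with `sim_meta` restored from the
#'   sidecar when present).
#' @export
write_twin_pairs <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  meta <- attr(data, "sim_meta")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_twin_pairs
#' @export
read_twin_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(df, "sim_meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  meas <- unique(sub("_[12]$", "", grep("^(?!age_|sex|family_id|zygosity|g_)",
                                        names(df), perl = TRUE, value = TRUE)))
  meas <- meas[paste0(meas, "_1") %in% names(df) &
                 paste0(meas, "_2") %in% names(df)]
  attr(df, "measures") <- meas
  class(df) <- c("twin_pairs", "data.frame")
  df
}

#' Write / read a genotype panel as tab-separated dosages
#'
#' First two columns are family and sample id (family id duplicates the
#' sample id for the unrelated panels simulated here), then one column of
#' 0/1/2 dosages per SNP with SNP ids in the header.
#'
#' @param panel A `genotype_panel`.
#' @param path TSV file path.
#' @return `write_genotype_panel` returns `path` invisibly;
#'   `read_genotype_panel` a `genotype_panel` (allele frequencies are
#'   recomputed from the sample; allele codes default to A/G as written by
#'   the simulator).
#' @export
write_genotype_panel <- function(panel, path) {
  df <- data.frame(FID = panel$sample_ids, IID = panel$sample_ids,
                   panel$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_panel
#' @export
read_genotype_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  dos <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(dos) <- df$IID
  m <- ncol(dos)
  structure(list(dosages = dos, allele_freqs = colMeans(dos) / 2,
                 snp_ids = colnames(dos), sample_ids = df$IID,
                 a1 = rep("A", m), a2 = rep("G", m), seed = NULL),
            class = "genotype_panel")
}

#' Read a 3-column SNP weight table
#'
#' Tab-separated `snp_id`, `effect_allele`, `weight` — the layout common
#' scoring files use. A header row is detected automatically.
#'
#' @param path File path.
#' @return Data frame with columns `snp_id`, `effect_allele`, `weight`.
#' @export
read_weight_table <- function(path) {
  first <- utils::read.table(path, nrows = 1, sep = "\t",
                             stringsAsFactors = FALSE)
  header <- suppressWarnings(is.na(as.numeric(first[[3]])))
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- c("snp_id", "effect_allele", "weight")
  df$weight <- as.numeric(df$weight)
  if (any(!is.finite(df$weight))) {
    stop("weight table contains non-finite weights", call. = FALSE)
  }
  df
}

#' Write a weight table
#' @param weights Data frame with `snp_id`, `effect_allele`, `weight`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path) {
  utils::write.table(weights[, c("snp_id", "effect_allele", "weight")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a GRM in the GCTA text convention
#'
#' `<prefix>.grm.gz` holds whitespace-separated triplets (row index, column
#' index, SNP count, relatedness) over the lower triangle including the
#' diagonal; `<prefix>.grm.id` the family/sample ids.
#'
#' @param grm A `grm` object.
#' @param prefix Path prefix for the two files.
#' @return `write_grm_gcta` returns `prefix` invisibly; `read_grm_gcta` a
#'   `grm` object.
#' @export
write_grm_gcta <- function(grm, prefix) {
  n <- nrow(grm$G)
  idx <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(
    data.frame(i = idx[, 1], j = idx[, 2], m = grm$n_snps,
               g = grm$G[idx]),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.table(data.frame(fid = grm$sample_ids, iid = grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")))
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(tri[[1]], tri[[2]])] <- tri[[4]]
  G[cbind(tri[[2]], tri[[1]])] <- tri[[4]]
  structure(list(G = G, sample_ids = ids, n_snps = tri[[3]][1]),
            class = "grm")
}
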