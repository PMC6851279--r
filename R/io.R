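# Readers and writers for the tidy study formats: long expression CSV,
# growth CSV, aligned FASTA (SNP extraction), distance-matrix CSV, and the
# study bundle with manifest.

#' Read a long-format expression CSV into landscapes
#'
#' Expects columns `strain, camp_mM, iptg_uM, replicate, afu` (units fixed
#' in the column names). Replicates are averaged per cell; per-cell
#' replicate counts and standard deviations are retained. Negative
#' background-subtracted values are clamped to zero with a warning; strains
#' with incomplete grids are accepted (missing cells become `NA` and are
#' masked during fitting).
#'
#' @param path CSV file path.
#' @return Named list of [expression_landscape()] objects.
#' @export
read_expression_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "camp_mM", "iptg_uM", "replicate", "afu")
  if (!all(need %in% colnames(df)))
    stop("expression CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in c("camp_mM", "iptg_uM", "afu")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop("non-numeric ", col, " at data row ", bad, call. = FALSE)
    }
  }
  key <- paste(df$strain, df$camp_mM, df$iptg_uM, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (strain, camp, iptg, replicate) rows, e.g. row ",
         which(duplicated(key))[1L], call. = FALSE)
  n_neg <- sum(df$afu < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative background-subtracted value(s) clamped to 0",
            call. = FALSE)
    df$afu[df$afu < 0] <- 0
  }
  out <- lapply(split(df, df$strain), function(d) {
    camp <- sort(unique(d$camp_mM))
    iptg <- sort(unique(d$iptg_uM))
    grid <- inducer_grid(camp, iptg)
    dims <- c(length(camp), length(iptg))
    mval <- msd <- matrix(NA_real_, dims[1L], dims[2L])
    mn <- matrix(0L, dims[1L], dims[2L])
    i <- match(d$camp_mM, camp); j <- match(d$iptg_uM, iptg)
    for (cell in split(seq_len(nrow(d)), paste(i, j))) {
      ii <- i[cell[1L]]; jj <- j[cell[1L]]
      vals <- d$afu[cell]
      mval[ii, jj] <- mean(vals)
      msd[ii, jj] <- if (length(vals) > 1L) sd(vals) else NA_real_
      mn[ii, jj] <- length(vals)
    }
    expression_landscape(d$strain[1L], grid, mval, n_replicates = mn,
                         sd = msd)
  })
  out
}

#' Write replicate-level expression data as a long CSV
#'
#' @param study A `"lac_study"` (uses the per-replicate draws) or a data
#'   frame already in long format.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(study, path) {
  df <- if (is.data.frame(study)) study else expression_long(study)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

expression_long <- function(study) {
  stopifnot(inherits(study, "lac_study"))
  grid <- study$config$grid
  do.call(rbind, lapply(seq_along(study$params), function(i) {
    reps <- study$replicates[[i]]
    do.call(rbind, lapply(seq_len(dim(reps)[3L]), function(r) {
      data.frame(strain = names(study$params)[i],
                 camp_mM = rep(grid$camp_mM, times = length(grid$iptg_uM)),
                 iptg_uM = rep(grid$iptg_uM, each = length(grid$camp_mM)),
                 replicate = r,
                 afu = as.vector(reps[, , r]))
    }))
  }))
}

#' Read a growth CSV into growth curves
#'
#' Expects columns `well, strain, time_min, od450`.
#'
#' @param path CSV file path.
#' @return List of [growth_curve()] objects (one per well).
#' @export
read_growth_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "strain", "time_min", "od450")
  if (!all(need %in% colnames(df)))
    stop("growth CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_min), ]
    growth_curve(d$well[1L], d$strain[1L], d$time_min, d$od450)
  })
}

#' @rdname read_growth_csv
#' @param curves List of [growth_curve()] objects.
#' @export
write_growth_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(g) {
    data.frame(well = g$well_id, strain = g$strain_id,
               time_min = g$times, od450 = g$od)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Extract a SNP matrix from an aligned FASTA file
#'
#' Reads an aligned FASTA (all sequences equal length; gaps allowed, and a
#' gap is kept as its own allele class), retains the polymorphic columns
#' and records their 1-based alignment coordinates.
#'
#' @param path Aligned FASTA path.
#' @return A [snp_matrix()].
#' @export
snp_matrix_from_alignment <- function(path) {
  aln <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  aln <- tolower(aln)
  poly <- apply(aln, 2L, function(col) length(unique(col)) >= 2L)
  if (!any(poly)) stop("alignment has no polymorphic sites", call. = FALSE)
  snp_matrix(aln[, poly, drop = FALSE], positions = which(poly))
}

#' Write a SNP matrix back into a padded aligned FASTA
#'
#' Produces an alignment whose polymorphic columns sit at the recorded
#' coordinates; all other columns are a monomorphic background base, so
#' [snp_matrix_from_alignment()] recovers the matrix and positions exactly.
#'
#' @param snps A [snp_matrix()].
#' @param path Output FASTA path.
#' @param length_out Total alignment length (default: max position + 10).
#' @return `path`, invisibly.
#' @export
write_snp_alignment <- function(snps, path, length_out = NULL) {
  stopifnot(inherits(snps, "snp_matrix"))
  L <- if (is.null(length_out)) max(snps$positions) + 10L else length_out
  n <- nrow(snps$alleles)
  mat <- matrix("a", n, L, dimnames = list(rownames(snps$alleles), NULL))
  mat[, snps$positions] <- snps$alleles
  lines <- character(2L * n)
  lines[seq(1L, by = 2L, length.out = n)] <- paste0(">", rownames(mat))
  lines[seq(2L, by = 2L, length.out = n)] <- apply(mat, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a labelled distance matrix as CSV
#'
#' @param D Symmetric labelled matrix.
#' @param path CSV path.
#' @return `write_distance_csv`: `path` invisibly; `read_distance_csv`: the
#'   matrix.
#' @export
write_distance_csv <- function(D, path) {
  write.csv(as.data.frame(D), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write a synthetic study to a bundle directory
#'
#' Emits `expression.csv`, `growth.csv`, `tree.nwk`, `alignment.fasta`,
#' `truth.json` (true parameters, lags and planted sites) and a
#' `manifest.json` recording the seed and MD5 checksums of every file.
#'
#' @param study A `"lac_study"` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "lac_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_csv(study, file.path(dir, "expression.csv"))
  write_growth_csv(study$growth_curves, file.path(dir, "growth.csv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  write_snp_alignment(study$snps, file.path(dir, "alignment.fasta"))
  truth <- list(seed = study$config$seed,
                params = lapply(study$params, function(p) as.list(unclass(p))),
                true_lags = as.list(study$true_lags),
                snp_registry = study$snp_registry)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("expression.csv", "growth.csv", "tree.nwk", "alignment.fasta",
             "truth.json")
  manifest <- list(seed = study$config$seed, files = as.list(
    setNames(unname(tools::md5sum(file.path(dir, files))), files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study bundle directory
#'
#' Loads whatever files are present (a partial bundle is allowed;
#' downstream stages skip with a logged reason) and verifies manifest
#' checksums when a manifest exists.
#'
#' @param dir Bundle directory.
#' @return A list of class `"lac_bundle"` with any of `landscapes`,
#'   `growth_curves`, `tree`, `snps`, `truth`, `seed`.
#' @export
read_study_bundle <- function(dir) {
  out <- list(dir = dir)
  mpath <- file.path(dir, "manifest.json")
  if (file.exists(mpath)) {
    manifest <- jsonlite::read_json(mpath)
    out$seed <- manifest$seed
    for (f in names(manifest$files)) {
      fp <- file.path(dir, f)
      if (file.exists(fp) &&
          !identical(unname(tools::md5sum(fp)), manifest$files[[f]]))
        stop("checksum mismatch for bundle file ", f, call. = FALSE)
    }
  }
  fp <- file.path(dir, "expression.csv")
  if (file.exists(fp)) out$landscapes <- read_expression_csv(fp)
  fp <- file.path(dir, "growth.csv")
  if (file.exists(fp)) out$growth_curves <- read_growth_csv(fp)
  fp <- file.path(dir, "tree.nwk")
  if (file.exists(fp)) out$tree <- ape::read.tree(fp)
  fp <- file.path(dir, "alignment.fasta")
  if (file.exists(fp)) out$snps <- snp_matrix_from_alignment(fp)
  fp <- file.path(dir, "truth.json")
  if (file.exists(fp)) out$truth <- jsonlite::read_json(fp, simplifyVector = TRUE)
  class(out) <- "lac_bundle"
  out
}
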