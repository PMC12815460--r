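# File formats: comma-separated CSV, UTF-8, '#'-prefixed key=value metadata
# lines, dot decimal separator. Concentrations are uM, volumes ml, shifts
# ppm at the I/O boundary; column names carry units.

.read_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$",
                           meta_lines))
  kv <- Filter(function(m) length(m) == 3L, kv)
  stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
}

.read_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop(sprintf("parse error in '%s': %s", path,
                                     conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop(sprintf("schema error: '%s' contains no data rows", path))
  df
}

.write_with_meta <- function(df, path, meta) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read and write titration series CSV
#'
#' Columns `ligand_total_uM`, `response_ppm`; the protein concentration and
#' resonance label travel in `# key=value` header comments
#' (`protein_total_uM`, `label`).
#'
#' @param series A [titration_series()].
#' @param path File path.
#' @return `read_titration_csv()` returns a [titration_series()];
#'   `write_titration_csv()` returns `path` invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  .write_with_meta(
    data.frame(ligand_total_uM = series$ligand_total,
               response_ppm = series$response),
    path,
    list(protein_total_uM = attr(series, "protein_total"),
         label = attr(series, "label")))
  invisible(path)
}

#' @rdname write_titration_csv
#' @param protein_total Override for the protein concentration (uM) when the
#'   file header lacks `protein_total_uM`.
#' @export
read_titration_csv <- function(path, protein_total = NULL) {
  meta <- .read_meta(path)
  df <- .read_table(path)
  need <- c("ligand_total_uM", "response_ppm")
  if (!all(need %in% names(df)))
    stop(sprintf("schema error: need columns %s; available: %s",
                 paste(need, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  pt <- protein_total
  if (is.null(pt) && !is.null(meta$protein_total_uM))
    pt <- as.numeric(meta$protein_total_uM)
  if (is.null(pt))
    stop("protein_total not given and no 'protein_total_uM' header in file")
  titration_series(df$ligand_total_uM, df$response_ppm, pt,
                   label = if (is.null(meta$label)) "" else meta$label)
}

#' Read and write peak list CSV
#'
#' Columns `residue_number, residue_type, atom_group, shift_h_ppm,
#' shift_x_ppm, intensity`; the condition label travels as a
#' `# condition_label=` header.
#'
#' @param pl A [peak_list()].
#' @param path File path.
#' @return `read_peak_list_csv()` returns a [peak_list()].
#' @export
write_peak_list_csv <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  .write_with_meta(as.data.frame(pl), path,
                   list(condition_label = attr(pl, "condition_label")))
  invisible(path)
}

#' @rdname write_peak_list_csv
#' @export
read_peak_list_csv <- function(path) {
  meta <- .read_meta(path)
  df <- .read_table(path)
  peak_list(df, condition_label = if (is.null(meta$condition_label)) ""
            else meta$condition_label)
}

#' Read a whitespace-separated assignment-style peak list
#'
#' Parses the common four-column export `label w1 w2 height` where the
#' label encodes residue type, number and atom names (e.g. `I377CD1-HD1`
#' for an Ile delta1 methyl, `T374N-H` for a backbone amide). `w1` is taken
#' as the heteronuclear (15N/13C) shift and `w2` as the 1H shift.
#'
#' @param path File path.
#' @param condition_label Label for the resulting [peak_list()].
#' @return A [peak_list()].
#' @export
read_assignment_list <- function(path, condition_label = "") {
  df <- .read_table(path, sep = "")
  if (ncol(df) < 4L)
    stop("schema error: expected 4 columns (label, w1, w2, height)")
  names(df)[1:4] <- c("label", "w1", "w2", "height")
  m <- regexec("^([A-Za-z])(\\d+)([A-Za-z0-9]+)-", paste0(df$label, "-"))
  parts <- regmatches(paste0(df$label, "-"), m)
  bad <- vapply(parts, length, 0L) != 4L
  if (any(bad))
    stop("unparsable label(s): ", paste(df$label[bad], collapse = ", "))
  atom <- toupper(vapply(parts, `[[`, "", 4L))
  peak_list(data.frame(
    residue_number = as.integer(vapply(parts, `[[`, "", 3L)),
    residue_type = toupper(vapply(parts, `[[`, "", 2L)),
    atom_group = ifelse(grepl("^CD1", atom), "ile_d1_methyl",
                        "backbone_amide"),
    shift_h_ppm = as.numeric(df$w2),
    shift_x_ppm = as.numeric(df$w1),
    intensity = as.numeric(df$height)), condition_label)
}

#' Read and write chromatogram CSV
#'
#' Columns `volume_ml`, `a280_AU`; trace label as a `# label=` header.
#'
#' @param chrom A [chromatogram()].
#' @param path File path.
#' @return `read_chromatogram_csv()` returns a [chromatogram()].
#' @export
write_chromatogram_csv <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  .write_with_meta(as.data.frame(chrom), path,
                   list(label = attr(chrom, "label")))
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  meta <- .read_meta(path)
  df <- .read_table(path)
  need <- c("volume_ml", "a280_AU")
  if (!all(need %in% names(df)))
    stop(sprintf("schema error: need columns %s; available: %s",
                 paste(need, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  chromatogram(df$volume_ml, df$a280_AU,
               label = if (is.null(meta$label)) "" else meta$label)
}

#' Read and write proteolysis time-course CSV
#'
#' Columns `time_min`, `full_length_AU`, `cleaved_AU`; condition label as a
#' `# label=` header. One file per condition.
#'
#' @param tc A [digestion_timecourse()].
#' @param path File path.
#' @return `read_timecourse_csv()` returns a [digestion_timecourse()].
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "digestion_timecourse"))
  .write_with_meta(as.data.frame(tc), path,
                   list(label = attr(tc, "label")))
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  meta <- .read_meta(path)
  df <- .read_table(path)
  need <- c("time_min", "full_length_AU", "cleaved_AU")
  if (!all(need %in% names(df)))
    stop(sprintf("schema error: need columns %s; available: %s",
                 paste(need, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  digestion_timecourse(df$time_min, df$full_length_AU, df$cleaved_AU,
                       label = if (is.null(meta$label)) "" else meta$label)
}

#' Read and write a two-channel image as TIFF
#'
#' Writes the receptor and arrestin channels as two 32-bit float pages of
#' one TIFF. Because float TIFF storage is defined on `[0, 1]`, intensities
#' are divided by `scale` on write and must be multiplied back on read;
#' TIFF carries no physical pixel size either, so both quantities travel
#' out of band (function arguments, or the truth/config JSON next to
#' generated images).
#'
#' @param img A [two_channel_image()].
#' @param path File path.
#' @param scale Normalization divisor; default the maximum intensity over
#'   both channels. Returned invisibly so callers can record it.
#' @return `read_two_channel_tiff()` returns a [two_channel_image()];
#'   `write_two_channel_tiff()` invisibly returns the scale used.
#' @export
write_two_channel_tiff <- function(img, path, scale = NULL) {
  stopifnot(inherits(img, "two_channel_image"))
  if (is.null(scale))
    scale <- max(img$receptor$pixels, img$arrestin$pixels, 1e-12)
  tiff::writeTIFF(list(img$receptor$pixels / scale,
                       img$arrestin$pixels / scale),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' @rdname write_two_channel_tiff
#' @param pixel_size_um Physical pixel size of the stored image (um).
#' @param scale Intensity multiplier undoing the writer's normalization
#'   (default 1).
#' @param paths Optional character vector of two single-page TIFFs
#'   (receptor, arrestin) instead of one two-page file.
#' @export
read_two_channel_tiff <- function(path = NULL, paths = NULL,
                                  pixel_size_um, scale = 1) {
  if (is.null(path) == is.null(paths))
    stop("give exactly one of 'path' (two-page TIFF) or 'paths' (two files)")
  pages <- if (!is.null(path)) {
    tiff::readTIFF(path, all = TRUE)
  } else {
    lapply(paths, tiff::readTIFF)
  }
  if (length(pages) != 2L)
    stop("expected exactly 2 image pages/files (receptor, arrestin)")
  as_mat <- function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first sample of multi-sample
    p * scale
  }
  two_channel_image(channel_image(as_mat(pages[[1]]), pixel_size_um),
                    channel_image(as_mat(pages[[2]]), pixel_size_um))
}

#' Build an attenuation profile from precomputed ratios
#'
#' For published per-residue `I/I0` tables (ratios only, no raw peak
#' lists): applies the same mean/SD/threshold significance machinery as
#' [intensity_ratios()].
#'
#' @param residue_number Integer residue numbers.
#' @param ratio Intensity ratios `I/I0`, >= 0.
#' @return An `attenuation_profile` (see [intensity_ratios()]).
#' @export
attenuation_profile_from_ratios <- function(residue_number, ratio) {
  stopifnot(length(residue_number) == length(ratio), all(ratio >= 0))
  entries <- data.frame(residue_number = as.integer(residue_number),
                        atom_group = NA_character_, ratio = as.numeric(ratio))
  mu <- mean(entries$ratio)
  sdv <- stats::sd(entries$ratio)
  if (is.na(sdv)) sdv <- 0
  thr <- mu - sdv
  structure(list(entries = entries, mean = mu, sd = sdv, threshold = thr,
                 significant = entries$residue_number[entries$ratio < thr],
                 excluded = character()),
            class = "attenuation_profile")
}

#' Build a CSP profile from precomputed perturbations
#'
#' Counterpart of [attenuation_profile_from_ratios()] for published
#' combined-perturbation tables; applies the mean + 1 SD rule of
#' [combined_csp()].
#'
#' @param residue_number Integer residue numbers.
#' @param csp Combined shift perturbations (ppm), >= 0.
#' @return A `csp_profile` (see [combined_csp()]).
#' @export
csp_profile_from_values <- function(residue_number, csp) {
  stopifnot(length(residue_number) == length(csp), all(csp >= 0))
  entries <- data.frame(residue_number = as.integer(residue_number),
                        atom_group = NA_character_, csp = as.numeric(csp))
  mu <- mean(entries$csp)
  sdv <- stats::sd(entries$csp)
  if (is.na(sdv)) sdv <- 0
  thr <- mu + sdv
  structure(list(entries = entries, mean = mu, sd = sdv, threshold = thr,
                 significant = entries$residue_number[entries$csp > thr],
                 excluded = character()),
            class = "csp_profile")
}

#' Load a figure source-data table with a configurable column mapping
#'
#' Published source-data CSVs come in unpredictable layouts; `mapping`
#' renames the file's columns onto the standard ones. Required standard
#' columns per kind: titration `ligand_total_uM`, `response_ppm`;
#' intensity_ratio `residue_number`, `ratio`; csp `residue_number`,
#' `csp_ppm`.
#'
#' @param path CSV/TSV file.
#' @param table_kind `"titration"`, `"intensity_ratio"`, or `"csp"`.
#' @param mapping Named list `standard_name = "file column name"`; standard
#'   names already present in the file need not be mapped.
#' @param protein_total Protein concentration (uM); required for
#'   `"titration"`.
#' @param label Label for the resulting object.
#' @param sep Field separator (default `","`; use `"\t"` for TSV).
#' @return A [titration_series()], `attenuation_profile`, or `csp_profile`.
#' @export
load_source_data <- function(path,
                             table_kind = c("titration", "intensity_ratio",
                                            "csp"),
                             mapping = list(), protein_total = NULL,
                             label = "", sep = ",") {
  table_kind <- match.arg(table_kind)
  df <- .read_table(path, sep = sep)
  for (std in names(mapping)) {
    src <- mapping[[std]]
    if (!src %in% names(df))
      stop(sprintf("schema error: mapped column '%s' not in file; available: %s",
                   src, paste(names(df), collapse = ", ")))
    names(df)[names(df) == src] <- std
  }
  need <- switch(table_kind,
                 titration = c("ligand_total_uM", "response_ppm"),
                 intensity_ratio = c("residue_number", "ratio"),
                 csp = c("residue_number", "csp_ppm"))
  if (!all(need %in% names(df)))
    stop(sprintf("schema error: need columns %s; available: %s",
                 paste(need, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  switch(table_kind,
         titration = {
           if (is.null(protein_total))
             stop("'protein_total' is required for titration tables")
           titration_series(df$ligand_total_uM, df$response_ppm,
                            protein_total, label = label)
         },
         intensity_ratio =
           attenuation_profile_from_ratios(df$residue_number, df$ratio),
         csp = csp_profile_from_values(df$residue_number, df$csp_ppm))
}
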