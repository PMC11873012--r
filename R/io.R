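#' Read and write CSF curves as CSV
#'
#' Two-column CSV (`nu`, `sensitivity`).
#'
#' @param curve a [CSFCurve-class].
#' @param path file path.
#' @return `readCSFCurve` returns a [CSFCurve-class]; `writeCSFCurve`
#'   returns the path invisibly.
#' @export
writeCSFCurve <- function(curve, path) {
  write.csv(data.frame(nu = curve@nus, sensitivity = curve@sensitivity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCSFCurve
#' @export
readCSFCurve <- function(path) {
  df <- read.csv(path)
  if (!all(c("nu", "sensitivity") %in% names(df)))
    stop("CSF CSV must have columns 'nu' and 'sensitivity'")
  csfCurve(df$nu, df$sensitivity)
}

#' Read and write accuracy matrices as labeled CSV
#'
#' Long-format CSV with one column per condition axis plus an `accuracy`
#' column; dimnames are restored on read.
#'
#' @param am an [AccuracyMatrix-class].
#' @param path file path.
#' @export
writeAccuracyMatrix <- function(am, path) {
  a <- accuracy(am)
  dn <- dimnames(a)
  if (is.null(dn)) dn <- lapply(dim(a), seq_len)
  names(dn) <- names(dimnames(a)) %||%
    paste0("axis", seq_along(dim(a)))
  df <- expand.grid(dn, stringsAsFactors = FALSE)
  df$accuracy <- as.numeric(a)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || any(is.na(a))) b else a

#' @rdname writeAccuracyMatrix
#' @export
readAccuracyMatrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"accuracy" %in% names(df))
    stop("accuracy CSV must have an 'accuracy' column")
  axes <- setdiff(names(df), "accuracy")
  dn <- lapply(df[axes], function(x) unique(as.character(x)))
  a <- array(NA_real_, dim = vapply(dn, length, 0L), dimnames = dn)
  pos <- mapply(function(col, lev) match(as.character(col), lev),
                df[axes], dn)
  a[as.matrix(pos)] <- df$accuracy
  accuracyMatrix(a, list(source = path))
}

#' Write a grayscale image as 8-bit PNG
#'
#' Presentation-only output; analyses use the full-precision in-memory
#' matrices.
#'
#' @param image matrix in \[0, 1\].
#' @param path file path.
#' @export
writeStimulusPNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname writeStimulusPNG
#' @export
readStimulusPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a saliency map with significance overlays as PNG
#'
#' Grayscale saliency with salient pixels tinted red and anti-salient
#' pixels tinted cyan.
#'
#' @param map a [SaliencyMap-class].
#' @param path file path.
#' @export
writeSaliencyPNG <- function(map, path) {
  s <- saliency(map)
  rng <- range(s, na.rm = TRUE)
  g <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else s * 0
  g[is.na(g)] <- 0
  rgb <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  sal <- salientMask(map)
  anti <- antisalientMask(map)
  rgb[, , 1][sal] <- 1
  rgb[, , 2][sal] <- 0.2 * g[sal]
  rgb[, , 3][sal] <- 0.2 * g[sal]
  rgb[, , 1][anti] <- 0.2 * g[anti]
  rgb[, , 2][anti] <- 1
  rgb[, , 3][anti] <- 1
  png::writePNG(rgb, path)
  invisible(path)
}

#' Load an optional reference pattern
#'
#' Reads a deposited reference artifact (a per-condition accuracy matrix
#' or a saliency map) from CSV and validates it against the corresponding
#' container's invariants.
#'
#' @param path CSV file.
#' @param kind `"accuracy_matrix"` or `"saliency_map"`.
#' @param source free-form provenance annotation (e.g. a DOI string).
#' @return list with `kind`, `payload`, `source`.
#' @export
loadReference <- function(path, kind = c("accuracy_matrix",
                                         "saliency_map"),
                          source = NA_character_) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- if (kind == "accuracy_matrix") {
    am <- readAccuracyMatrix(path)
    if (any(accuracy(am) < 0 | accuracy(am) > 1, na.rm = TRUE))
      stop("invalid field 'accuracy': values outside [0, 1]")
    am
  } else {
    df <- read.csv(path)
    if (!all(c("row", "col", "S") %in% names(df)))
      stop("invalid saliency CSV: need columns 'row', 'col', 'S'")
    side <- max(df$row)
    S <- matrix(NA_real_, side, max(df$col))
    S[cbind(df$row, df$col)] <- df$S
    S
  }
  list(kind = kind, payload = payload, source = source)
}

#' Save an experiment report with a manifest
#'
#' Writes every artifact of a report into a directory (CSV for accuracy
#' matrices and data frames, RDS for everything else, PNG for saliency
#' maps) plus a `manifest.json` listing each file with its type, an MD5
#' checksum (`tools::md5sum`) and the MD5 hash of the serialized
#' provenance. If any write fails, partially written files are removed.
#'
#' @param report an [ExperimentReport-class].
#' @param directory output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
saveReport <- function(report, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  entries <- list()
  on_fail <- function(e) {
    unlink(written)
    stop("saveReport failed (partial files removed): ",
         conditionMessage(e))
  }
  tryCatch({
    for (nm in names(report@artifacts)) {
      art <- report@artifacts[[nm]]
      if (is(art, "AccuracyMatrix")) {
        f <- file.path(directory, paste0(nm, ".csv"))
        writeAccuracyMatrix(art, f)
        type <- "accuracy_matrix"
      } else if (is(art, "SaliencyMap")) {
        f <- file.path(directory, paste0(nm, ".rds"))
        saveRDS(art, f)
        writeSaliencyPNG(art, file.path(directory, paste0(nm, ".png")))
        written <- c(written, file.path(directory, paste0(nm, ".png")))
        type <- "saliency_map"
      } else if (is.data.frame(art)) {
        f <- file.path(directory, paste0(nm, ".csv"))
        write.csv(art, f, row.names = FALSE)
        type <- "data_frame"
      } else {
        f <- file.path(directory, paste0(nm, ".rds"))
        saveRDS(art, f)
        type <- "rds"
      }
      written <- c(written, f)
      entries[[length(entries) + 1L]] <-
        list(file = basename(f), type = type,
             md5 = unname(tools::md5sum(f)))
    }
    prov_file <- tempfile()
    saveRDS(report@provenance, prov_file)
    manifest <- list(experiment = report@experiment,
                     hashAlgorithm = "md5",
                     configHash = unname(tools::md5sum(prov_file)),
                     artifacts = entries)
    unlink(prov_file)
    jsonlite::write_json(manifest,
                         file.path(directory, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
  }, error = on_fail)
}

#' Read an augmentation configuration from YAML
#'
#' Expected keys: `d_cm`, `screen_cm` (w, h), `res_px` (w, h),
#' `pose_spans_deg` (pitch, roll, yaw), `sigma_blur_px`, `sigma_noise`,
#' optional `ppd`.
#'
#' @param path YAML file.
#' @return an [AugmentationConfig-class].
#' @export
readAugmentationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- viewingGeometry(
    d = y$d_cm %||% 30,
    screenW = y$screen_cm[[1]] %||% 48, screenH = y$screen_cm[[2]] %||% 27,
    resW = y$res_px[[1]] %||% 224L, resH = y$res_px[[2]] %||% 224L,
    ppd = y$ppd %||% (224 / 96))
  ranges <- headPoseRanges(y$pose_spans_deg[[1]] %||% 60,
                           y$pose_spans_deg[[2]] %||% 35,
                           y$pose_spans_deg[[3]] %||% 20)
  nb <- noiseBlurParams(y$sigma_blur_px %||% 0, y$sigma_noise %||% 0)
  augmentationConfig(ranges, geom, nb)
}

#' Write a stimulus manifest CSV
#'
#' Records, for a set of rendered stimuli, the generating parameters and
#' file names: (object_id, size_deg, azimuth_deg, inplane_deg,
#' hshift_deg, style, file).
#'
#' @param entries data.frame with those columns.
#' @param path CSV path.
#' @export
writeStimulusManifest <- function(entries, path) {
  need <- c("object_id", "size_deg", "azimuth_deg", "inplane_deg",
            "hshift_deg", "style", "file")
  if (!all(need %in% names(entries)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  write.csv(entries[need], path, row.names = FALSE)
  invisible(path)
}
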