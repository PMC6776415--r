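# file formats: TCK streamlines, NIfTI volumes, delimited-text connectomes,
# cohort CSV, JSON results

#' Write streamlines in TCK (MRtrix tracks) format
#'
#' Binary little-endian Float32 triplets, streamlines separated by a NaN
#' triplet and the file terminated by an Inf triplet, after a plain-text
#' key: value header.
#'
#' @param tracks A [streamline_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tracks, path) {
  stopifnot(inherits(tracks, "streamline_set"))
  n <- length(tracks$streamlines)
  header_fmt <- function(offset) {
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
           "\nfile: . ", offset, "\nEND\n")
  }
  # header length depends on the offset digits; iterate to a fixed point
  offset <- nchar(header_fmt(0))
  repeat {
    new_offset <- nchar(header_fmt(offset))
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header_fmt(offset), con, eos = NULL)
  for (sl in tracks$streamlines) {
    writeBin(as.numeric(t(sl)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read streamlines from a TCK file
#'
#' @param path TCK file path.
#' @return A [streamline_set()].
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  end_tag <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(end_tag) == 0L) {
    abort(sprintf("'%s': no END marker in TCK header.", path))
  }
  header <- rawToChar(raw[seq_len(end_tag[1] + 3L)])
  lines <- strsplit(header, "\n")[[1]]
  if (lines[1] != "mrtrix tracks") {
    abort(sprintf("'%s' is not a TCK file (bad magic line).", path))
  }
  kv <- lines[grepl(":", lines, fixed = TRUE)]
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  dt <- vals[keys == "datatype"]
  if (length(dt) && !dt %in% c("Float32LE", "Float32")) {
    abort(sprintf("unsupported TCK datatype '%s'.", dt))
  }
  off_field <- vals[keys == "file"]
  if (!length(off_field)) abort("TCK header lacks a 'file' field.")
  offset <- as.integer(sub("^\\.\\s+", "", off_field[1]))
  xyz <- readBin(raw[-seq_len(offset)], "numeric", size = 4L,
                 n = (length(raw) - offset) / 4L, endian = "little")
  pts <- matrix(xyz, ncol = 3L, byrow = TRUE)
  is_sep <- is.nan(pts[, 1L])
  is_end <- is.infinite(pts[, 1L])
  streamlines <- list()
  start <- 1L
  for (r in seq_len(nrow(pts))) {
    if (is_sep[r] || is_end[r]) {
      if (r > start) {
        streamlines[[length(streamlines) + 1L]] <-
          pts[start:(r - 1L), , drop = FALSE]
      }
      start <- r + 1L
      if (is_end[r]) break
    }
  }
  streamline_set(streamlines)
}

#' Write a tensor field or label volume as NIfTI
#'
#' Tensor fields are stored as 4-D volumes with 6 lower-triangular components
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz); parcellations as integer 3-D label
#' volumes.
#'
#' @param x A [tensor_field()] or `parcellation`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "tensor_field")) {
    img <- RNifti::asNifti(x$tensors, pixdim = c(x$voxel_size, 1))
    RNifti::writeNifti(img, path)
  } else if (inherits(x, "parcellation")) {
    img <- RNifti::asNifti(x$labels, pixdim = x$voxel_size,
                           datatype = "int16")
    RNifti::writeNifti(img, path)
  } else {
    abort("`x` must be a tensor_field or parcellation.")
  }
  invisible(path)
}

#' Read a tensor field from NIfTI
#'
#' @param path NIfTI path of a 4-D 6-component tensor volume.
#' @param mask Optional logical mask array.
#' @return A [tensor_field()].
#' @export
read_tensor_nifti <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  tensor_field(arr, voxel_size = vs, mask = mask)
}

#' Read a parcellation from NIfTI
#'
#' @param path NIfTI path of an integer label volume (0 = background).
#' @return A `parcellation` (volumes recomputed from voxel counts).
#' @export
read_parcellation_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  labs <- sort(unique(labels[labels > 0]))
  if (!identical(labs, seq_len(max(labs)))) {
    abort(sprintf("'%s': labels must be contiguous 1..n.", path))
  }
  vols <- as.numeric(table(factor(labels[labels > 0], levels = labs))) * prod(vs)
  structure(
    list(labels = labels, voxel_size = vs, affine = diag(c(vs, 1)),
         volumes = setNames(vols, labs)),
    class = "parcellation"
  )
}

#' Write / read a connectome as delimited text
#'
#' The weight matrix (and count matrix when present) are tab-separated
#' matrices; node volumes go to a one-column file; a JSON sidecar records the
#' strategy and matrix files.
#'
#' @param conn A [connectome()].
#' @param dir Output directory (created if needed).
#' @param name File stem (default `"connectome"`).
#' @return The sidecar path, invisibly.
#' @export
write_connectome <- function(conn, dir, name = "connectome") {
  stopifnot(inherits(conn, "connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(strategy = conn$strategy, n_nodes = conn$n_nodes)
  wpath <- file.path(dir, paste0(name, "_weights.tsv"))
  utils::write.table(conn$weights, wpath, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  files$weights <- basename(wpath)
  if (!is.null(conn$counts)) {
    cpath <- file.path(dir, paste0(name, "_counts.tsv"))
    utils::write.table(conn$counts, cpath, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    files$counts <- basename(cpath)
  }
  if (!is.null(conn$volumes)) {
    vpath <- file.path(dir, paste0(name, "_volumes.tsv"))
    utils::write.table(data.frame(volume_mm3 = conn$volumes), vpath,
                       sep = "\t", row.names = FALSE)
    files$volumes <- basename(vpath)
  }
  side <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(files, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}

#' @rdname write_connectome
#' @param sidecar Path to the JSON sidecar written by [write_connectome()].
#' @export
read_connectome <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  read_mat <- function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  }
  w <- unname(read_mat(meta$weights))
  counts <- if (!is.null(meta$counts)) {
    m <- unname(read_mat(meta$counts))
    storage.mode(m) <- "integer"
    m
  }
  vols <- if (!is.null(meta$volumes)) {
    v <- utils::read.table(file.path(dir, meta$volumes), sep = "\t",
                           header = TRUE)
    setNames(v$volume_mm3, seq_len(nrow(v)))
  }
  connectome(meta$n_nodes, counts = counts, volumes = vols, weights = w,
             strategy = meta$strategy)
}

#' Write / read a cohort covariate table as CSV
#'
#' Missing cognitive or disease cells round-trip as empty fields and are
#' honoured downstream by pairwise deletion.
#'
#' @param covs Covariate tibble (see [simulate_cohort()]).
#' @param path CSV path.
#' @return `path` invisibly, or the tibble for the reader.
#' @export
write_cohort_csv <- function(covs, path) {
  readr::write_csv(covs, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  covs <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  if ("group" %in% names(covs)) {
    covs$group <- factor(covs$group, levels = unique(covs$group))
  }
  covs
}
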