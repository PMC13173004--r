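# Minimal NRRD0004 I/O for scalar volumes and label maps.
# Supports the subset this toolkit writes: 3-D arrays, little-endian raw or
# ascii encoding, diagonal space directions. No installed R package reads
# NRRD, hence the in-package implementation.

#' Write a volume to a NRRD file
#'
#' @param image an `image3`, or a numeric/integer 3D array (then `spacing` and
#'   `origin` must be given).
#' @param path output file path.
#' @param encoding `"raw"` (little-endian binary) or `"ascii"`.
#' @param spacing,origin grid metadata, taken from `image` when it is an
#'   `image3`.
#' @param content free-text `content:` header field (e.g. units).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(image, path, encoding = c("raw", "ascii"),
                       spacing = NULL, origin = NULL, content = NULL) {
  encoding <- match.arg(encoding)
  if (inherits(image, "image3")) {
    vals <- image$values; spacing <- image$spacing; origin <- image$origin
  } else {
    vals <- image
    if (is.null(spacing) || is.null(origin))
      stop("write_nrrd: spacing and origin required for bare arrays")
  }
  stopifnot(length(dim(vals)) == 3L)
  is_int <- is.integer(vals)
  type <- if (is_int) "int" else "double"
  hdr <- c(
    "NRRD0004",
    if (!is.null(content)) paste0("content: ", content),
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(vals), collapse = " ")),
    "space: left-posterior-superior",
    paste0("space directions: ",
           paste(sprintf("(%.9g,%.9g,%.9g)",
                         c(spacing[1], 0, 0), c(0, spacing[2], 0),
                         c(0, 0, spacing[3])), collapse = " ")),
    paste0("space origin: ", sprintf("(%.9g,%.9g,%.9g)",
                                     origin[1], origin[2], origin[3])),
    "endian: little",
    paste0("encoding: ", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.vector(vals), con, size = if (is_int) 4L else 8L,
             endian = "little")
  } else {
    writeLines(paste(format(as.vector(vals), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     collapse = "\n"), con)
  }
  invisible(path)
}

#' Read a NRRD volume written by [write_nrrd()]
#'
#' @param path NRRD file path.
#' @return an `image3` (values coerced to numeric; integer label maps keep
#'   integer storage in `$values`).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic)) stop("read_nrrd: not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("read_nrrd: truncated header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- kv[3]
  }
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("read_nrrd: only 3-D volumes supported")
  type <- fields[["type"]]
  encoding <- fields[["encoding"]]
  n <- prod(sizes)
  vals <- switch(
    encoding,
    raw = readBin(con, what = if (type == "int") integer() else numeric(),
                  n = n, size = if (type == "int") 4L else 8L,
                  endian = "little"),
    ascii = {
      txt <- readLines(con)
      v <- as.numeric(scan(text = paste(txt, collapse = "\n"), quiet = TRUE))
      if (type == "int") as.integer(v) else v
    },
    stop("read_nrrd: unsupported encoding '", encoding, "'")
  )
  if (length(vals) != n) stop("read_nrrd: data length mismatch")
  parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  origin <- if (!is.null(fields[["space origin"]]))
    parse_vec(fields[["space origin"]]) else c(0, 0, 0)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(dirs, parse_vec, numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  img <- image3(array(as.numeric(vals), dim = sizes), spacing = spacing,
                origin = origin)
  if (type == "int") img$values <- array(as.integer(vals), dim = sizes)
  img
}

#' Write a structure set as a label map plus JSON sidecar
#'
#' Voxels are labelled with the highest-priority structure containing them
#' (target first, then non-body structures, then body). The sidecar records,
#' for every structure, the set of labels composing its mask (so nested
#' structures such as body round-trip losslessly) together with its
#' (alpha/beta)_x.
#'
#' @param structures a `structure_set`.
#' @param image the `image3` supplying grid metadata.
#' @param path label-map NRRD path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param encoding passed to [write_nrrd()].
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, image, path, encoding = "raw") {
  nms <- names(structures$masks)
  # priority for labelling: target > other non-body > body
  prio <- c(structures$target,
            setdiff(nms, c(structures$target, "body")),
            intersect("body", nms))
  labels <- seq_along(prio)
  names(labels) <- prio
  lab <- array(0L, dim = structures$dims)
  for (nm in rev(prio)) lab[structures$masks[[nm]]] <- labels[[nm]]
  # a structure's mask is recoverable as the union of the labels whose
  # voxels fall inside it (labelling uses the highest-priority structure,
  # so nested masks span several labels)
  composition <- lapply(nms, function(nm)
    unname(labels[vapply(prio, function(p)
      any(lab == labels[[p]] & structures$masks[[nm]]), logical(1))]))
  names(composition) <- nms
  write_nrrd(lab, path, encoding = encoding, spacing = image$spacing,
             origin = image$origin, content = "structure label map")
  sidecar <- list(
    labels = stats::setNames(as.list(prio), as.character(labels)),
    composition = composition,
    alpha_beta = as.list(structures$alpha_beta),
    target = structures$target
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a structure set written by [write_structures()]
#'
#' @param path label-map NRRD path (sidecar expected at `path.json`).
#' @return a `structure_set`.
#' @export
read_structures <- function(path) {
  lab <- read_nrrd(path)$values
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  masks <- lapply(sc$composition, function(ls) array(lab %in% ls, dim = dim(lab)))
  structure_set(masks, alpha_beta = unlist(sc$alpha_beta), target = sc$target)
}
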