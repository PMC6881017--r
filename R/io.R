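#' Read a landmark coordinate table
#'
#' Supported dialects:
#' \describe{
#'   \item{`long`}{CSV/TSV with columns `specimen, point, x, y, z`
#'     (one row per point).}
#'   \item{`wide`}{CSV/TSV with one specimen per row: a `specimen` column
#'     followed by `x1,y1,z1,...,xp,yp,zp`.}
#'   \item{`tps`}{TPS format with `LM3=` blocks and optional `ID=` keys.}
#' }
#' With `dialect = "auto"` the dialect is sniffed from the first line.
#' Separator (comma vs tab) is sniffed for the tabular dialects.
#'
#' @param path Path to the file.
#' @param scheme `landmark_scheme` the configurations must match.
#' @param dialect `"auto"`, `"long"`, `"wide"` or `"tps"`.
#' @return A `shape_dataset`. Specimen ids come from the file, or are
#'   synthesized as zero-padded indices in file order when absent.
#' @export
read_landmark_table <- function(path, scheme,
                                dialect = c("auto", "long", "wide", "tps")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("^LM3?=", first)) "tps"
      else if (grepl("(^|[,\t])point([,\t]|$)", tolower(first))) "long"
      else "wide"
  }
  p <- n_points(scheme)
  dat <- switch(dialect,
    long = .read_long(path, p),
    wide = .read_wide(path, p),
    tps = .read_tps(path, p))
  shape_dataset(dat$coords, scheme, ids = dat$ids)
}

.sniff_sep <- function(line) if (grepl("\t", line)) "\t" else ","

.read_long <- function(path, p) {
  sep <- .sniff_sep(readLines(path, n = 1L, warn = FALSE))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("specimen", "point", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("long table must have columns specimen, point, x, y, z", call. = FALSE)
  for (v in c("x", "y", "z"))
    if (!is.numeric(tab[[v]]))
      stop("parse error: non-numeric values in column '", v, "'", call. = FALSE)
  ids <- unique(as.character(tab$specimen))
  coords <- array(NA_real_, dim = c(p, 3L, length(ids)))
  for (i in seq_along(ids)) {
    block <- tab[as.character(tab$specimen) == ids[i], , drop = FALSE]
    if (nrow(block) != p)
      stop("specimen '", ids[i], "' has ", nrow(block),
           " points; scheme requires ", p, call. = FALSE)
    block <- block[order(block$point), , drop = FALSE]
    coords[, , i] <- as.matrix(block[, c("x", "y", "z")])
  }
  list(coords = coords, ids = ids)
}

.read_wide <- function(path, p) {
  sep <- .sniff_sep(readLines(path, n = 1L, warn = FALSE))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  has_id <- tolower(names(tab)[1]) == "specimen"
  ids <- if (has_id) as.character(tab[[1]]) else sprintf("spec%03d", seq_len(nrow(tab)))
  num <- as.matrix(tab[, if (has_id) -1L else TRUE, drop = FALSE])
  if (!is.numeric(num)) stop("parse error: non-numeric coordinate cell", call. = FALSE)
  if (ncol(num) %% 3L != 0L)
    stop("wide table coordinate count (", ncol(num), ") not divisible by 3",
         call. = FALSE)
  if (ncol(num) / 3L != p) {
    # per-specimen message: all rows share the width, report the first id
    stop("specimen '", ids[1], "' has ", ncol(num) / 3L,
         " points; scheme requires ", p, call. = FALSE)
  }
  n <- nrow(num)
  coords <- array(NA_real_, dim = c(p, 3L, n))
  for (i in seq_len(n))
    coords[, , i] <- matrix(num[i, ], ncol = 3L, byrow = TRUE)
  list(coords = coords, ids = ids)
}

.read_tps <- function(path, p) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^LM3?=", lines)
  if (!length(starts)) stop("no LM= blocks found in TPS file", call. = FALSE)
  ids <- character(0); blocks <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]
    m <- as.integer(sub("^LM3?=", "", lines[s]))
    end <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    body <- lines[(s + 1L):end]
    idline <- grep("^ID=", body, value = TRUE)
    coordlines <- body[!grepl("^[A-Z]+=", body)]
    if (length(coordlines) != m)
      stop("TPS block ", k, ": LM=", m, " but ", length(coordlines),
           " coordinate lines", call. = FALSE)
    xyz <- t(vapply(strsplit(trimws(coordlines), "[ \t]+"),
                    function(v) as.numeric(v[1:3]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("parse error in TPS block ", k, ": non-numeric coordinate",
           call. = FALSE)
    if (m != p)
      stop("specimen '", if (length(idline)) sub("^ID=", "", idline[1]) else k,
           "' has ", m, " points; scheme requires ", p, call. = FALSE)
    ids[k] <- if (length(idline)) sub("^ID=", "", idline[1]) else sprintf("spec%03d", k)
    blocks[[k]] <- xyz
  }
  list(coords = array(unlist(blocks), dim = c(p, 3L, length(blocks))), ids = ids)
}

#' Write a landmark coordinate table
#'
#' Inverse of [read_landmark_table()]; round-trips coordinates at full
#' double precision (17 significant digits) for every dialect.
#'
#' @param dataset A `shape_dataset`.
#' @param path Output path.
#' @param dialect `"long"`, `"wide"` or `"tps"`.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(dataset, path,
                                 dialect = c("long", "wide", "tps")) {
  stopifnot(inherits(dataset, "shape_dataset"))
  dialect <- match.arg(dialect)
  co <- dataset$coords
  p <- dim(co)[1]; n <- dim(co)[3]
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "long") {
    writeLines("specimen,point,x,y,z", con)
    for (i in seq_len(n))
      writeLines(paste(dataset$ids[i], seq_len(p), fmt(co[, 1, i]),
                       fmt(co[, 2, i]), fmt(co[, 3, i]), sep = ","), con)
  } else if (dialect == "wide") {
    writeLines(paste(c("specimen",
                       paste0(rep(c("x", "y", "z"), p), rep(seq_len(p), each = 3))),
                     collapse = ","), con)
    for (i in seq_len(n))
      writeLines(paste(c(dataset$ids[i], fmt(as.vector(t(co[, , i])))),
                       collapse = ","), con)
  } else {
    for (i in seq_len(n)) {
      writeLines(paste0("LM3=", p), con)
      writeLines(paste(fmt(co[, 1, i]), fmt(co[, 2, i]), fmt(co[, 3, i])), con)
      writeLines(paste0("ID=", dataset$ids[i]), con)
    }
  }
  invisible(path)
}

#' Read / write a specimen metadata table
#'
#' CSV with columns `specimen_id`, `species` and optionally `genus`.
#' `attach_metadata()` joins it onto a dataset by specimen id.
#'
#' @param path CSV path.
#' @return `read_metadata` returns a data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(md) <- tolower(names(md))
  if (!all(c("specimen_id", "species") %in% names(md)))
    stop("metadata needs columns specimen_id, species", call. = FALSE)
  md
}

#' @rdname read_metadata
#' @param dataset A `shape_dataset`.
#' @param metadata Data.frame as returned by `read_metadata`.
#' @return `attach_metadata` returns the dataset with species/genus filled in.
#' @export
attach_metadata <- function(dataset, metadata) {
  i <- match(dataset$ids, metadata$specimen_id)
  if (anyNA(i))
    stop("metadata missing specimens: ",
         paste(dataset$ids[is.na(i)], collapse = ", "), call. = FALSE)
  shape_dataset(dataset$coords, dataset$scheme,
                species = metadata$species[i],
                genus = if ("genus" %in% names(metadata)) metadata$genus[i],
                ids = dataset$ids)
}
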