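#' Foci within one nucleus
#'
#' A `foci_set` holds all detected FISH/IF foci of one or more channels within
#' a single nucleus, as physical 3D coordinates in micrometres, together with
#' the bounding-sphere radius used as the null geometry for spatial tests.
#'
#' @param foci data frame with columns `channel` (character), `x_um`, `y_um`,
#'   `z_um` (numeric, micrometres); extra columns (e.g. `parent_id`) are kept.
#'   May have zero rows.
#' @param nucleus_id identifier for the nucleus.
#' @param bounding_radius bounding-sphere radius in micrometres (default 5,
#'   the radius used for all nuclei in the clustering analyses).
#' @param metadata optional named list of free-form metadata.
#'
#' @return An object of class `foci_set`: a list with elements `nucleus_id`,
#'   `foci`, `bounding_radius`, `metadata`.
#' @examples
#' fs <- foci_set(data.frame(channel = "EGFR",
#'                           x_um = c(0, 1), y_um = 0, z_um = 0))
#' n_foci(fs)
#' @export
foci_set <- function(foci, nucleus_id = "nucleus_1", bounding_radius = 5,
                     metadata = list()) {
  if (!is.data.frame(foci)) stop("'foci' must be a data frame", call. = FALSE)
  required <- c("channel", "x_um", "y_um", "z_um")
  missing <- setdiff(required, names(foci))
  if (length(missing) > 0) {
    stop("foci table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  foci <- as.data.frame(foci)
  foci$channel <- as.character(foci$channel)
  for (col in c("x_um", "y_um", "z_um")) {
    if (!is.numeric(foci[[col]]) || anyNA(foci[[col]]) ||
        any(!is.finite(foci[[col]]))) {
      stop(sprintf("column '%s' must be finite numeric", col), call. = FALSE)
    }
  }
  assert_scalar_number(bounding_radius, "bounding_radius", 0, strict_lower = TRUE)
  structure(list(nucleus_id = nucleus_id, foci = foci,
                 bounding_radius = bounding_radius, metadata = metadata),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> nucleus '%s': %d foci, bounding radius %g um\n",
              as.character(x$nucleus_id), nrow(x$foci), x$bounding_radius))
  tab <- table(x$foci$channel)
  if (length(tab) > 0) {
    cat("  channels:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of foci in a foci_set
#' @param x a [foci_set].
#' @param channel optional channel label; default counts all channels.
#' @return integer count.
#' @export
n_foci <- function(x, channel = NULL) {
  stopifnot(inherits(x, "foci_set"))
  if (is.null(channel)) return(nrow(x$foci))
  sum(x$foci$channel == channel)
}

# coordinate matrix (n x 3) for a channel selection; channel = NULL -> all
foci_coords <- function(x, channel = NULL) {
  stopifnot(inherits(x, "foci_set"))
  f <- x$foci
  if (!is.null(channel)) {
    unknown <- setdiff(channel, unique(f$channel))
    if (length(unknown) > 0 && nrow(f) > 0) {
      stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    f <- f[f$channel %in% channel, , drop = FALSE]
  }
  as.matrix(f[, c("x_um", "y_um", "z_um"), drop = FALSE])
}

#' Read a foci coordinate table into foci_set objects
#'
#' Reads a CSV in the interchange layout used throughout the package (one row
#' per detected focus, the layout of a typical spot-detection export):
#' columns `nucleus_id`, `channel`, `x_um`, `y_um`, `z_um`; extra columns are
#' preserved. Returns one [foci_set] per nucleus.
#'
#' @param path path to the CSV file.
#' @param bounding_radius bounding radius (um) recorded on every nucleus.
#' @return named list of [foci_set], one per `nucleus_id`.
#' @seealso [write_foci_table()]
#' @export
read_foci_table <- function(path, bounding_radius = 5) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("nucleus_id", "channel", "x_um", "y_um", "z_um")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("foci table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("x_um", "y_um", "z_um")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf("non-numeric value in column '%s' at data row(s): %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  ids <- unique(tab$nucleus_id)
  out <- lapply(ids, function(id) {
    rows <- tab[tab$nucleus_id == id, setdiff(names(tab), "nucleus_id"),
                drop = FALSE]
    rownames(rows) <- NULL
    foci_set(rows, nucleus_id = id, bounding_radius = bounding_radius)
  })
  names(out) <- as.character(ids)
  out
}

#' Write foci_set objects to a CSV coordinate table
#'
#' @param x a [foci_set] or list of them.
#' @param path output CSV path.
#' @param digits decimal places for coordinates (default 4).
#' @return `path`, invisibly.
#' @export
write_foci_table <- function(x, path, digits = 4) {
  if (inherits(x, "foci_set")) x <- list(x)
  rows <- lapply(x, function(fs) {
    f <- fs$foci
    if (nrow(f) == 0) return(NULL)
    for (col in c("x_um", "y_um", "z_um")) f[[col]] <- round(f[[col]], digits)
    cbind(nucleus_id = fs$nucleus_id, f)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) stop("no foci to write", call. = FALSE)
  # nuclei may carry different extra columns (e.g. parent_id, pair_id);
  # write the union, padding with NA
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
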