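#' Electrode montage with a predetermined channel-name list
#'
#' An ordered set of named contacts. The allowed-name list mirrors the
#' channel names extracted from a recording file: contacts can only be
#' marked under one of these names, which eliminates naming mismatches
#' between the recording and the localization.
#'
#' @param names Character vector of unique channel names (the predetermined
#'   list).
#' @param positions Optional n x 3 matrix of mm positions (NA rows =
#'   unlocated).
#' @param frame Frame tag of located positions.
#' @return An object of class `ielec_montage` with elements `contacts`
#'   (data.frame: name, x, y, z, status), `allowed_names`, `frame`.
#' @export
montage <- function(names, positions = NULL, frame = "mr_subject") {
  names <- as.character(names)
  if (anyDuplicated(names))
    ielec_stop("name", "duplicate channel names: %s",
               paste(unique(names[duplicated(names)]), collapse = ", "))
  n <- length(names)
  if (is.null(positions)) positions <- matrix(NA_real_, n, 3)
  positions <- as_points(positions)
  if (nrow(positions) != n)
    ielec_stop("dim", "positions rows (%d) != number of names (%d)",
               nrow(positions), n)
  located <- stats::complete.cases(positions)
  if (any(located & !is.finite(rowSums(positions[, , drop = FALSE]))))
    ielec_stop("dim", "located positions must be finite")
  structure(list(
    contacts = data.frame(name = names, x = positions[, 1], y = positions[, 2],
                          z = positions[, 3],
                          status = ifelse(located, "located", "unlocated"),
                          stringsAsFactors = FALSE),
    allowed_names = names,
    frame = match.arg(frame, .FRAMES)
  ), class = "ielec_montage")
}

#' @export
print.ielec_montage <- function(x, ...) {
  cat(sprintf("<ielec_montage> %d contacts (%d located), frame %s\n",
              nrow(x$contacts), sum(x$contacts$status == "located"), x$frame))
  invisible(x)
}

#' Positions of located contacts
#' @param m An `ielec_montage`.
#' @param names Optional subset of contact names (default: all located).
#' @return n x 3 matrix with rownames = contact names.
#' @export
montage_positions <- function(m, names = NULL) {
  cc <- m$contacts
  if (!is.null(names)) {
    miss <- setdiff(names, cc$name)
    if (length(miss))
      ielec_stop("name", "unknown contact(s): %s", paste(miss, collapse = ", "))
    cc <- cc[match(names, cc$name), ]
  } else cc <- cc[cc$status == "located", ]
  out <- as.matrix(cc[, c("x", "y", "z")])
  rownames(out) <- cc$name
  out
}

#' Mark a contact at a position
#'
#' Associates a channel name with a 3D location. The name must belong to the
#' montage's predetermined list; close misspellings are suggested. Re-marking
#' an already-located contact overwrites its position with a message.
#'
#' @param m An `ielec_montage`.
#' @param name Channel name (must be in `m$allowed_names`).
#' @param at A [snap_to_center()] result or a 3-vector of mm coordinates.
#' @return The updated montage.
#' @export
mark_contact <- function(m, name, at) {
  if (!name %in% m$allowed_names) {
    d <- drop(adist(name, m$allowed_names))
    near <- m$allowed_names[d <= 2]
    hint <- if (length(near)) sprintf("; did you mean %s?",
                                      paste(shQuote(near), collapse = ", ")) else ""
    ielec_stop("name", "unknown channel name %s%s", shQuote(name), hint)
  }
  pos <- if (inherits(at, "ielec_snap")) at$center else as_points(at)[1, ]
  if (!all(is.finite(pos))) ielec_stop("dim", "contact position must be finite")
  i <- match(name, m$contacts$name)
  if (m$contacts$status[i] == "located")
    message(sprintf("re-marking %s: position overwritten", name))
  m$contacts[i, c("x", "y", "z")] <- as.list(pos)
  m$contacts$status[i] <- "located"
  m
}

#' Read / write a BIDS-iEEG style electrodes.tsv
#'
#' Tab-separated with header `name x y z` (mm). Unlocated contacts are
#' written with `n/a` coordinates per BIDS convention; coordinates are
#' written with three decimal places.
#'
#' @param path File path.
#' @param frame Frame tag to attach on read.
#' @return `read_electrodes_tsv` returns an `ielec_montage`.
#' @export
read_electrodes_tsv <- function(path, frame = "mr_subject") {
  if (!file.exists(path)) ielec_stop("io", "electrodes file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "n/a",
                   check.names = FALSE)
  need <- c("name", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ielec_stop("format", "electrodes.tsv missing column(s): %s",
               paste(miss, collapse = ", "))
  montage(df$name, cbind(as.numeric(df$x), as.numeric(df$y), as.numeric(df$z)),
          frame = frame)
}

#' @rdname read_electrodes_tsv
#' @param m An `ielec_montage`.
#' @export
write_electrodes_tsv <- function(m, path) {
  cc <- m$contacts
  fmt <- function(v) ifelse(is.na(v), "n/a", sprintf("%.3f", v))
  out <- data.frame(name = cc$name, x = fmt(cc$x), y = fmt(cc$y), z = fmt(cc$z))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("name", "x", "y", "z"), collapse = "\t"), con)
  writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}
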