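#' Read a FreeSurfer-style color lookup table
#'
#' Whitespace-delimited lines `id name R G B A`; `#` comments and blank
#' lines are ignored. Id 0 is reserved for "Unknown" and added if absent.
#'
#' @param path File path.
#' @return An `ielec_lut`: data.frame with columns id, name, r, g, b, a.
#' @export
read_lut <- function(path) {
  if (!file.exists(path)) ielec_stop("io", "LUT file not found: %s", path)
  ln <- readLines(path)
  ln_clean <- sub("#.*$", "", ln)
  keep <- which(nzchar(trimws(ln_clean)))
  if (length(keep)) {
    parts <- strsplit(trimws(ln_clean[keep]), "\\s+")
    bad <- which(lengths(parts) < 6L)
    if (length(bad))
      ielec_stop("format", "LUT line %d has fewer than 6 fields", keep[bad[1]])
    df <- data.frame(
      id = as.integer(vapply(parts, `[`, "", 1L)),
      name = vapply(parts, `[`, "", 2L),
      r = as.integer(vapply(parts, `[`, "", 3L)),
      g = as.integer(vapply(parts, `[`, "", 4L)),
      b = as.integer(vapply(parts, `[`, "", 5L)),
      a = as.integer(vapply(parts, `[`, "", 6L)),
      line = keep, stringsAsFactors = FALSE)
    dup <- df$id[duplicated(df$id)]
    if (length(dup)) {
      lines <- df$line[df$id == dup[1]]
      ielec_stop("format", "duplicate label id %d on lines %s", dup[1],
                 paste(lines, collapse = " and "))
    }
  } else {
    df <- data.frame(id = integer(), name = character(), r = integer(),
                     g = integer(), b = integer(), a = integer(),
                     line = integer(), stringsAsFactors = FALSE)
  }
  if (!0L %in% df$id)
    df <- rbind(data.frame(id = 0L, name = "Unknown", r = 0L, g = 0L, b = 0L,
                           a = 0L, line = NA_integer_), df)
  df <- df[order(df$id), setdiff(names(df), "line")]
  rownames(df) <- NULL
  class(df) <- c("ielec_lut", "data.frame")
  df
}

lut_name <- function(lut, ids) {
  nm <- lut$name[match(ids, lut$id)]
  nm[is.na(nm)] <- "Unknown"
  nm
}

#' Anatomical label fractions at positions
#'
#' Samples the segmentation in a world-mm ball of the given radius around
#' each position and reports the fraction of sampled voxels carrying each
#' label. Radius 0 takes the single nearest voxel. Positions outside the
#' volume get `Unknown` with fraction 1. Fractions per position sum to 1 and
#' are sorted descending, ties broken by lower label id.
#'
#' @param seg Label-kind `ielec_volume`.
#' @param lut An `ielec_lut`.
#' @param positions n x 3 matrix (or 3-vector), world mm.
#' @param radius Sampling radius in mm (default 2); 0 for nearest voxel.
#' @return List (one element per position) of data.frames with columns
#'   `id`, `label`, `fraction`.
#' @export
labels_at_positions <- function(seg, lut, positions, radius = 2) {
  if (seg$kind != "label")
    ielec_stop("kind", "segmentation volume must be kind=label")
  if (radius < 0) ielec_stop("bounds", "radius must be >= 0")
  pts <- as_points(positions)
  dm <- dim(seg$data)
  unknown <- data.frame(id = 0L, label = lut_name(lut, 0L), fraction = 1)
  lapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    vx <- world_to_voxel(seg, p)
    if (radius == 0) {
      vi <- round(vx)
      if (any(vi < 0) || any(vi > dm - 1)) return(unknown)
      id <- seg$data[matrix(as.integer(vi) + 1L, 1)]
      return(data.frame(id = as.integer(id), label = lut_name(lut, id),
                        fraction = 1))
    }
    if (any(vx < -0.5) || any(vx > dm - 0.5)) return(unknown)
    b <- ball_voxels(seg, p, radius)
    if (is.null(b)) return(unknown)
    tab <- table(b$val)
    ids <- as.integer(names(tab))
    fr <- as.numeric(tab) / sum(tab)
    o <- order(-fr, ids)
    data.frame(id = ids[o], label = lut_name(lut, ids[o]), fraction = fr[o])
  })
}

#' Deep-to-superficial label sequence along an sEEG shaft
#'
#' Contacts named `<prefix><number>` are ordered by ascending number
#' (contact 1 is deepest, at the electrode tip) and each is assigned its
#' dominant anatomical label.
#'
#' @param seg,lut,radius As in [labels_at_positions()].
#' @param m `ielec_montage`; all shaft contacts must be located.
#' @param shaft Name prefix selecting the shaft (e.g. `"LPM"`).
#' @return data.frame with columns `name`, `number`, `label`, `fraction`
#'   (dominant label's fraction), ordered deep to superficial.
#' @export
shaft_label_sequence <- function(seg, lut, m, shaft, radius = 2) {
  cc <- m$contacts
  grp <- cc[startsWith(cc$name, shaft), , drop = FALSE]
  if (!nrow(grp)) ielec_stop("name", "no contacts with prefix %s", shQuote(shaft))
  suffix <- substring(grp$name, nchar(shaft) + 1L)
  if (any(!grepl("^[0-9]+$", suffix)))
    ielec_stop("name", "non-numeric contact suffix in shaft %s: %s",
               shQuote(shaft),
               paste(grp$name[!grepl("^[0-9]+$", suffix)], collapse = ", "))
  num <- as.integer(suffix)
  if (any(grp$status != "located"))
    ielec_stop("state", "unlocated contact(s) in shaft %s: %s", shQuote(shaft),
               paste(grp$name[grp$status != "located"], collapse = ", "))
  o <- order(num)
  grp <- grp[o, ]; num <- num[o]
  if (any(diff(num) != 1L))
    message(sprintf("shaft %s has gaps in contact numbering", shaft))
  labs <- labels_at_positions(seg, lut, as.matrix(grp[, c("x", "y", "z")]),
                              radius = radius)
  data.frame(name = grp$name, number = num,
             label = vapply(labs, function(d) d$label[1], ""),
             fraction = vapply(labs, function(d) d$fraction[1], 0),
             stringsAsFactors = FALSE)
}

#' Write contact label fractions as TSV
#'
#' One row per contact-label pair: `name label fraction`.
#'
#' @param names Character vector of contact names (parallel to `labels`).
#' @param labels Result of [labels_at_positions()].
#' @param path Output path.
#' @export
write_labels_tsv <- function(names, labels, path) {
  rows <- do.call(rbind, lapply(seq_along(labels), function(i)
    data.frame(name = names[i], label = labels[[i]]$label,
               fraction = sprintf("%.6f", labels[[i]]$fraction))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("name\tlabel\tfraction", con)
  writeLines(do.call(paste, c(rows, sep = "\t")), con)
  invisible(path)
}
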