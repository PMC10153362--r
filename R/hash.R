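## 6-D rigid-transform hashing: bin the rotation (intrinsic ZYX Euler angles)
## and translation of a transform into an integer key of a multi-value table
## mapping to motif rebuild records.

#' Binning specification for 6-D transform hashing
#'
#' Half-open bin cells: a value v falls in cell floor(v / bin). Translations
#' are binned componentwise over [-range, range); rotations via ZYX Euler
#' angles (yaw, roll in [-180, 180), pitch in [-90, 90]).
#'
#' @param translation_bin bin width, A (default 1.0).
#' @param rotation_bin bin width, degrees (default 15).
#' @param translation_range half-width of the binnable translation box, A.
#' @return object of class \code{bin_spec}.
#' @export
bin_spec <- function(translation_bin = 1.0, rotation_bin = 15,
                     translation_range = 32) {
  stopifnot(translation_bin > 0, rotation_bin > 0, translation_range > 0)
  structure(list(translation_bin = translation_bin, rotation_bin = rotation_bin,
                 translation_range = translation_range, scheme = "euler-zyx/v1"),
            class = "bin_spec")
}

#' ZYX Euler angles of a rotation matrix (degrees)
#' @param R 3x3 rotation matrix.
#' @return c(yaw, pitch, roll); at gimbal lock (|pitch| = 90) roll is set to 0.
#' @export
euler_zyx <- function(R) {
  sp <- max(-1, min(1, -R[3, 1]))
  pitch <- asin(sp)
  if (abs(sp) > 1 - 1e-12) {
    yaw <- atan2(-R[1, 2], R[2, 2])
    roll <- 0
  } else {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  }
  rad2deg(c(yaw, pitch, roll))
}

#' Hash a rigid transform into an integer key
#'
#' Deterministic: transforms in the same bin cell share the key. The six bin
#' indices are packed into one integer-valued double (field widths fit well
#' inside 53 bits for the default spec). Translations outside the configured
#' range give the out-of-range sentinel \code{NA}.
#'
#' @param t \code{rigid_transform}; @param bins \code{bin_spec}.
#' @return numeric scalar key, or NA if out of range.
#' @export
hash_transform <- function(t, bins = bin_spec()) {
  tb <- bins$translation_bin; rb <- bins$rotation_bin; rng <- bins$translation_range
  tr <- t$translation
  if (any(tr < -rng | tr >= rng)) return(NA_real_)
  it <- floor((tr + rng) / tb)
  nt <- ceiling(2 * rng / tb)
  e <- euler_zyx(t$rotation)
  iy <- floor((e[1] + 180) / rb); ny <- ceiling(360 / rb) + 1
  ip <- floor((e[2] + 90) / rb);  np_ <- ceiling(180 / rb) + 1
  ir <- floor((e[3] + 180) / rb)
  key <- ((((it[1] * nt + it[2]) * nt + it[3]) * ny + iy) * np_ + ip) * ny + ir
  key
}

#' Multi-value transform hash table
#' @param bins \code{bin_spec}.
#' @return empty \code{transform_hash_table}.
#' @export
transform_hash_table <- function(bins = bin_spec()) {
  structure(list(env = new.env(parent = emptyenv()), bins = bins, n = 0L),
            class = "transform_hash_table")
}

#' @export
print.transform_hash_table <- function(x, ...) {
  cat("transform_hash_table:", x$n, "record(s),",
      length(ls(x$env)), "key(s); bins", x$bins$translation_bin, "A /",
      x$bins$rotation_bin, "deg\n")
  invisible(x)
}

#' Insert a record under a transform
#' @param table \code{transform_hash_table}; @param t \code{rigid_transform};
#' @param record any value (normally a motif record).
#' @return the table (records are appended in insertion order).
#' @export
hash_insert <- function(table, t, record) {
  key <- hash_transform(t, table$bins)
  if (is.na(key)) stop("transform translation out of binnable range")
  k <- as.character(key)
  table$env[[k]] <- c(table$env[[k]], list(record))
  table$n <- table$n + 1L
  table
}

#' Query the table with a transform
#' @param table \code{transform_hash_table}; @param t \code{rigid_transform}.
#' @param neighbors if TRUE, also query the 3^3 neighboring translation cells
#'   (off by default).
#' @return list of records stored under the matching key(s) (possibly empty).
#' @export
hash_query <- function(table, t, neighbors = FALSE) {
  key <- hash_transform(t, table$bins)
  if (is.na(key)) return(list())
  if (!neighbors) {
    r <- table$env[[as.character(key)]]
    return(if (is.null(r)) list() else r)
  }
  tb <- table$bins$translation_bin
  out <- list()
  seen <- character(0)
  for (dx in c(-1, 0, 1) * tb) for (dy in c(-1, 0, 1) * tb)
    for (dz in c(-1, 0, 1) * tb) {
      t2 <- rigid_transform(t$rotation, t$translation + c(dx, dy, dz))
      k <- hash_transform(t2, table$bins)
      if (is.na(k)) next
      ks <- as.character(k)
      if (ks %in% seen) next
      seen <- c(seen, ks)
      r <- table$env[[ks]]
      if (!is.null(r)) out <- c(out, r)
    }
  out
}

#' Build a motif hash table
#'
#' One insertion per motif: the key is the binned 6-D transform between the
#' two ligating histidines' N-CA-C frames, the value the motif's rebuild
#' record.
#'
#' @param motifs non-empty list of \code{his_chl_motif}.
#' @param bins \code{bin_spec}.
#' @return populated \code{transform_hash_table}.
#' @export
build_table <- function(motifs, bins = bin_spec()) {
  if (!length(motifs)) stop("empty motif list")
  tab <- transform_hash_table(bins)
  for (m in motifs)
    tab <- hash_insert(tab, motif_transform(m), motif_record(m))
  tab
}

#' Serialize a hash table (records must be motif records)
#' @param table \code{transform_hash_table}; @param path output path.
#' @export
write_table <- function(table, path) {
  keys <- ls(table$env)
  rows <- list()
  for (k in keys) for (r in table$env[[k]])
    rows[[length(rows) + 1L]] <- cbind(data.frame(key = k), as.data.frame(r))
  df <- do.call(rbind, rows)
  hdr <- sprintf("# bin_spec\ttranslation_bin=%g\trotation_bin=%g\ttranslation_range=%g\tscheme=%s",
                 table$bins$translation_bin, table$bins$rotation_bin,
                 table$bins$translation_range, table$bins$scheme)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a hash table written by \code{\link{write_table}}
#' @param path file path.
#' @return \code{transform_hash_table} with motif records.
#' @export
read_table <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# bin_spec")) stop("not a transform hash table file")
  kv <- strsplit(strsplit(hdr, "\t")[[1]][-1], "=")
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  if (vals$scheme != "euler-zyx/v1") stop("unknown binning scheme: ", vals$scheme)
  bins <- bin_spec(as.numeric(vals$translation_bin), as.numeric(vals$rotation_bin),
                   as.numeric(vals$translation_range))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE,
                          colClasses = c(key = "character"))
  tab <- transform_hash_table(bins)
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, setdiff(names(df), "key")])
    k <- df$key[i]
    tab$env[[k]] <- c(tab$env[[k]], list(rec))
    tab$n <- tab$n + 1L
  }
  tab
}
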