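#' Read a surface mesh from OFF or ASCII PLY
#'
#' OFF files carry an "OFF" header line, a counts line
#' (vertices faces edges) and then vertex and face records; PLY support
#' covers the ASCII 1.0 dialect with `vertex` and `face` elements. Both
#' formats index vertices from 0; indices are shifted to 1-based on read.
#'
#' @param path file path.
#' @param format `"off"`, `"ply"`, or `"auto"` (by file extension, falling
#'   back to the file's magic line).
#' @param validate,closed passed to [surface_mesh()]; use
#'   `validate = FALSE` to load a broken mesh for inspection.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply"),
                      validate = TRUE, closed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("off", "ply")) ext else {
      first <- toupper(trimws(readLines(path, n = 1L)))
      if (identical(first, "OFF")) "off" else if (identical(first, "PLY")) "ply"
      else stop("cannot determine mesh format of ", path)
    }
  }
  mesh <- switch(format, off = read_off(path), ply = read_ply(path))
  if (validate) validate_mesh(mesh, closed = closed)
  mesh
}

read_off <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1L]) != "OFF")
    stop("line 1: expected 'OFF' header in ", path)
  cnt <- suppressWarnings(as.integer(strsplit(ln[2L], "\\s+")[[1L]]))
  if (length(cnt) < 2L || anyNA(cnt[1:2]))
    stop("line 2: malformed counts line in ", path)
  nv <- cnt[1L]; nf <- cnt[2L]
  if (length(ln) < 2L + nv + nf)
    stop(sprintf("file truncated: expected %d vertex + %d face lines", nv, nf))
  vtx <- ln[2L + seq_len(nv)]
  vm <- matrix(suppressWarnings(as.numeric(unlist(strsplit(vtx, "\\s+")))),
               ncol = 3L, byrow = TRUE)
  if (anyNA(vm)) stop(sprintf("line %d: malformed vertex record",
                              2L + which(is.na(rowSums(vm)))[1L]))
  fln <- ln[2L + nv + seq_len(nf)]
  fl <- strsplit(fln, "\\s+")
  sizes <- vapply(fl, function(x) as.integer(x[1L]), integer(1))
  if (any(sizes != 3L))
    stop(sprintf("line %d: only triangular faces are supported (got %d-gon)",
                 2L + nv + which(sizes != 3L)[1L], sizes[sizes != 3L][1L]))
  fm <- matrix(as.integer(unlist(lapply(fl, `[`, 2:4))), ncol = 3L, byrow = TRUE)
  surface_mesh(vm, fm + 1L, validate = FALSE)
}

read_ply <- function(path) {
  ln <- readLines(path)
  if (toupper(trimws(ln[1L])) != "PLY") stop("line 1: expected 'ply' header")
  hdr_end <- which(trimws(ln) == "end_header")[1L]
  if (is.na(hdr_end)) stop("PLY header has no end_header line")
  hdr <- trimws(ln[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported")
  el <- grep("^element\\s", hdr, value = TRUE)
  getn <- function(name) {
    m <- grep(paste0("^element\\s+", name, "\\s"), hdr, value = TRUE)
    if (length(m) == 0L) stop("PLY header lacks element ", name)
    as.integer(strsplit(m[1L], "\\s+")[[1L]][3L])
  }
  nv <- getn("vertex"); nf <- getn("face")
  body <- ln[(hdr_end + 1L):length(ln)]
  body <- body[nzchar(trimws(body))]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), "\\s+"))),
               nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  sizes <- vapply(fl, function(x) as.integer(x[1L]), integer(1))
  if (any(sizes != 3L)) stop("only triangular PLY faces are supported")
  fm <- matrix(as.integer(unlist(lapply(fl, `[`, 2:4))), ncol = 3L, byrow = TRUE)
  surface_mesh(vm, fm + 1L, validate = FALSE)
}

#' Write a surface mesh to OFF or ASCII PLY
#'
#' Coordinates are written with 17 significant digits (shortest
#' round-trip), "." decimal separator and LF line endings, so a write/read
#' cycle reproduces the mesh to 1e-12 and re-runs are byte-identical.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format `"off"` or `"ply"`.
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path, format = c("off", "ply")) {
  format <- match.arg(format)
  v <- mesh$vertices
  tr <- mesh$triangles - 1L
  vl <- sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L])
  fl <- sprintf("3 %d %d %d", tr[, 1L], tr[, 2L], tr[, 3L])
  out <- if (format == "off") {
    c("OFF", sprintf("%d %d 0", nrow(v), nrow(tr)), vl, fl)
  } else {
    c("ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(tr)),
      "property list uchar int vertex_indices", "end_header", vl, fl)
  }
  write_lines_lf(out, path)
  invisible(path)
}

#' Read a per-vertex region atlas from CSV
#'
#' The label file has header `vertex,region` with one row per mesh vertex,
#' vertex ids 0-based ascending. The side-car lobe table has header
#' `region,name,lobe,source_excluded` (source_excluded 0/1) and must cover
#' every region present in the labels.
#'
#' @param path label CSV path.
#' @param mesh the [surface_mesh()] the labels refer to.
#' @param lobe_table path of the lobe-table CSV.
#' @return a [region_atlas()].
#' @export
read_atlas <- function(path, mesh, lobe_table) {
  lab <- utils::read.csv(path)
  if (!all(c("vertex", "region") %in% names(lab)))
    stop("atlas CSV must have header 'vertex,region'")
  if (nrow(lab) != n_vertices(mesh))
    stop(sprintf("atlas has %d rows but mesh has %d vertices",
                 nrow(lab), n_vertices(mesh)))
  if (!identical(as.integer(lab$vertex), 0:(n_vertices(mesh) - 1L)))
    stop("atlas vertex ids must be 0-based ascending 0..n-1")
  lt <- utils::read.csv(lobe_table, colClasses = c(lobe = "character", name = "character"))
  need <- c("region", "name", "lobe", "source_excluded")
  if (!all(need %in% names(lt)))
    stop("lobe table must have header 'region,name,lobe,source_excluded'")
  ids <- sort(unique(as.integer(lab$region)))
  miss <- setdiff(ids, as.integer(lt$region))
  if (length(miss) > 0L)
    stop("lobe table missing region ", miss[1L])
  region_atlas(labels = as.integer(lab$region),
               region_names = stats::setNames(lt$name, lt$region),
               lobes = stats::setNames(lt$lobe, lt$region),
               source_excluded = as.integer(lt$region[lt$source_excluded == 1]))
}

#' Write an atlas (labels + lobe table) to CSV
#'
#' @param atlas a [region_atlas()].
#' @param path label CSV path (`vertex,region`, 0-based vertex ids).
#' @param lobe_table path for the side-car lobe table.
#' @return invisibly `path`.
#' @export
write_atlas <- function(atlas, path, lobe_table) {
  write_lines_lf(c("vertex,region",
                   sprintf("%d,%d", seq_along(atlas$labels) - 1L, atlas$labels)),
                 path)
  exc <- as.integer(atlas$region_ids %in% atlas$source_excluded)
  write_lines_lf(c("region,name,lobe,source_excluded",
                   sprintf("%d,%s,%s,%d", atlas$region_ids, atlas$region_names,
                           atlas$lobes, exc)),
                 lobe_table)
  invisible(path)
}

# locale-independent LF writer used by every text artifact
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

# 17-significant-digit CSV matrix writer with name header row/column
write_matrix_csv <- function(mat, path, row_label = "region") {
  stopifnot(!is.null(colnames(mat)))
  hdr <- paste(c(row_label, colnames(mat)), collapse = ",")
  rows <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = ","),
    character(1))
  write_lines_lf(c(hdr, rows), path)
  invisible(path)
}
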