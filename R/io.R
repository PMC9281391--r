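# Extended-XYZ and CIF input/output.
#
# Extended XYZ: lattice and per-structure key/value labels live on the
# comment line (Lattice="..." Properties=... energy=... virial="..."
# pbc="T T T"); per-atom forces are extra columns. The reader tolerates
# missing labels and plain XYZ files.

# parse key=value tokens, values optionally double-quoted
parse_kv_line <- function(line) {
  out <- list()
  pat <- "([A-Za-z_][A-Za-z0-9_]*)=(\"[^\"]*\"|[^\\s]+)"
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (k in seq_along(m)) {
    tok <- substr(line, m[k], m[k] + attr(m, "match.length")[k] - 1L)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1L, eq - 1L)
    val <- substr(tok, eq + 1L, nchar(tok))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

#' Read structures from an extended-XYZ file
#'
#' @param path file path.
#' @return a list of [periodic_structure()] objects (one per frame), each
#'   carrying energy/force/virial labels when present in the file.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed extxyz: expected atom count at line ", i)
    kv <- parse_kv_line(lines[i + 1L])
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    species <- vapply(toks, `[[`, "", 1L)
    ncol_body <- length(toks[[1]])
    num <- t(vapply(toks, function(tt) as.numeric(tt[-1L]),
                    numeric(ncol_body - 1L)))
    if (nat == 1L) num <- matrix(num, nrow = 1L)
    pos <- num[, 1:3, drop = FALSE]
    forces <- NULL
    if (!is.null(kv$Properties)) {
      pr <- strsplit(kv$Properties, ":")[[1]]
      off <- 0L
      for (k in seq(1L, length(pr), by = 3L)) {
        w <- as.integer(pr[k + 2L])
        nm <- pr[k]
        if (nm == "pos") pos <- num[, off + 1:3, drop = FALSE]
        if (nm %in% c("forces", "force")) {
          forces <- num[, off + 1:3, drop = FALSE]
        }
        if (nm != "species") off <- off + w
      }
    } else if (ncol_body >= 7L) {
      forces <- num[, 4:6, drop = FALSE]
    }
    cell <- NULL; pbc <- FALSE
    if (!is.null(kv$Lattice)) {
      cell <- matrix(as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]]),
                     3L, 3L, byrow = TRUE)
      pbc <- TRUE
    }
    if (!is.null(kv$pbc)) {
      pbc <- toupper(strsplit(trimws(kv$pbc), "\\s+")[[1]]) %in% c("T", "TRUE")
    }
    energy <- if (!is.null(kv$energy)) as.numeric(kv$energy) else NULL
    virial <- NULL
    if (!is.null(kv$virial)) {
      virial <- matrix(as.numeric(strsplit(trimws(kv$virial), "\\s+")[[1]]),
                       3L, 3L, byrow = TRUE)
      virial <- (virial + t(virial)) / 2
    }
    labels <- NULL
    if (!is.null(energy) || !is.null(forces) || !is.null(virial)) {
      labels <- efs_result(if (is.null(energy)) NA_real_ else energy,
                           forces, virial)
      if (is.null(energy)) labels$energy <- NULL
    }
    st <- periodic_structure(species, pos, cell = cell, pbc = pbc,
                             labels = labels, provenance = path)
    out[[length(out) + 1L]] <- st
    i <- i + 2L + nat
  }
  out
}

#' Write structures to an extended-XYZ file
#'
#' @param structures a [periodic_structure()] or list thereof.
#' @param path output path.
#' @export
write_extxyz <- function(structures, path) {
  if (inherits(structures, "periodic_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(sprintf("%.10f", x), collapse = " ")
  for (st in structures) {
    n <- n_atoms(st)
    has_f <- !is.null(st$labels$forces)
    props <- if (has_f) "species:S:1:pos:R:3:forces:R:3" else "species:S:1:pos:R:3"
    comment <- sprintf('Lattice="%s" Properties=%s pbc="%s"',
                       fmt(as.vector(t(st$cell))), props,
                       paste(ifelse(st$pbc, "T", "F"), collapse = " "))
    if (!is.null(st$labels$energy)) {
      comment <- sprintf("%s energy=%.10f", comment, st$labels$energy)
    }
    if (!is.null(st$labels$virial)) {
      comment <- sprintf('%s virial="%s"', comment,
                         fmt(as.vector(t(st$labels$virial))))
    }
    writeLines(c(sprintf("%d", n), comment), con)
    for (a in seq_len(n)) {
      row <- sprintf("%-3s %s", st$species[a], fmt(st$positions[a, ]))
      if (has_f) row <- paste(row, fmt(st$labels$forces[a, ]))
      writeLines(row, con)
    }
  }
  invisible(path)
}

# cell parameters (a, b, c, alpha, beta, gamma in degrees) -> 3x3 row cell
cell_from_parameters <- function(a, b, c3, alpha, beta, gamma) {
  d2r <- pi / 180
  ca <- cos(alpha * d2r); cb <- cos(beta * d2r); cg <- cos(gamma * d2r)
  sg <- sin(gamma * d2r)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cg, b * sg, 0)
  cx <- c3 * cb
  cy <- c3 * (ca - cb * cg) / sg
  cz <- sqrt(max(c3^2 - cx^2 - cy^2, 0))
  rbind(v1, v2, c(cx, cy, cz), deparse.level = 0)
}

# evaluate one CIF symmetry operation string like "-y, x-y, z+1/2"
apply_symop <- function(op, frac) {
  parts <- strsplit(gsub("'", "", op), ",")[[1]]
  vapply(seq_len(3L), function(k) {
    expr <- parse(text = tolower(parts[k]))[[1]]
    eval(expr, list(x = frac[1], y = frac[2], z = frac[3]))
  }, numeric(1))
}

#' Read a crystal structure from a CIF file
#'
#' Parses cell parameters, fractional atom sites and (when present)
#' symmetry operations, expanding the asymmetric unit to P1. Duplicate
#' generated sites (within 0.5 A) are merged.
#'
#' @param path file path.
#' @return a fully periodic [periodic_structure()].
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_num <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\b"), lines, value = TRUE)
    if (!length(ln)) stop("CIF missing ", key)
    val <- strsplit(trimws(ln[1]), "\\s+")[[1]][2]
    as.numeric(gsub("\\(.*\\)", "", val))
  }
  cell <- cell_from_parameters(get_num("_cell_length_a"),
                               get_num("_cell_length_b"),
                               get_num("_cell_length_c"),
                               get_num("_cell_angle_alpha"),
                               get_num("_cell_angle_beta"),
                               get_num("_cell_angle_gamma"))
  # locate loop_ blocks
  symops <- "x, y, z"
  loop_starts <- grep("^\\s*loop_", lines)
  for (ls in loop_starts) {
    hdr <- character(); i <- ls + 1L
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      hdr <- c(hdr, trimws(lines[i])); i <- i + 1L
    }
    body <- character()
    while (i <= length(lines) && nzchar(trimws(lines[i])) &&
           !grepl("^\\s*(_|loop_|data_|#)", lines[i])) {
      body <- c(body, trimws(lines[i])); i <- i + 1L
    }
    if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                  hdr))) {
      k <- grep("as_xyz|operation_xyz", hdr)
      symops <- vapply(body, function(b) {
        b <- gsub("^[0-9]+\\s+", "", b)       # optional leading index
        gsub("^'|'$", "", trimws(b))
      }, "")
      names(symops) <- NULL
    }
    if (any(grepl("_atom_site_fract_x", hdr))) {
      cols <- sub("^_", "", hdr)
      toks <- strsplit(body, "\\s+")
      tab <- t(vapply(toks, function(tt) tt[seq_along(cols)],
                      character(length(cols))))
      colnames(tab) <- cols
      sp_col <- if ("atom_site_type_symbol" %in% cols) {
        "atom_site_type_symbol"
      } else "atom_site_label"
      species0 <- gsub("[0-9+-].*$", "", tab[, sp_col])
      frac0 <- cbind(as.numeric(gsub("\\(.*\\)", "", tab[, "atom_site_fract_x"])),
                     as.numeric(gsub("\\(.*\\)", "", tab[, "atom_site_fract_y"])),
                     as.numeric(gsub("\\(.*\\)", "", tab[, "atom_site_fract_z"])))
      site_species <- species0
      site_frac <- frac0
    }
  }
  if (!exists("site_frac", inherits = FALSE)) stop("CIF has no atom sites")
  species <- character(); frac <- matrix(0, 0, 3)
  for (s in seq_len(nrow(site_frac))) {
    for (op in symops) {
      f <- apply_symop(op, site_frac[s, ]) %% 1
      if (nrow(frac)) {
        df <- sweep(frac, 2L, f)
        df <- df - round(df)
        cart <- df %*% cell
        if (any(sqrt(rowSums(cart^2)) < 0.5 &
                species == site_species[s])) next
      }
      species <- c(species, site_species[s])
      frac <- rbind(frac, f)
    }
  }
  periodic_structure(species, frac %*% cell, cell = cell, pbc = TRUE,
                     provenance = path)
}
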