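#' Read a structural model (PDB or mmCIF)
#'
#' Thin wrapper over [bio3d::read.pdb()] / [bio3d::read.cif()] that normalises
#' the atom records into a single data frame. Gzip-compressed files are
#' decompressed transparently.
#'
#' @param path Path to a `.pdb`, `.cif` (or `.gz` thereof) file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return An object of class `eet_structure`: a list with `atoms` (data frame
#'   with columns `type`, `chain`, `resno`, `resid`, `elety`, `elesy`, `alt`,
#'   `o`, `x`, `y`, `z`) and `source` (the input path).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  real <- path
  name <- path
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    name <- sub("\\.gz$", "", path, ignore.case = TRUE)
    real <- tempfile(fileext = paste0(".", tools::file_ext(name)))
    on.exit(unlink(real), add = TRUE)
    con <- gzfile(path, "rb")
    raw <- readBin(con, "raw", n = file.info(path)$size * 50L)
    close(con)
    writeBin(raw, real)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(name))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "cif", mmcif = "cif",
      stop("cannot infer structure format from extension '.", ext,
           "'; pass format = \"pdb\" or \"cif\"")
    )
  }
  mdl <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(real, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(real, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("failed to parse ", format, " file '", path,
                               "': ", conditionMessage(w), call. = FALSE)
  )
  at <- mdl$atom
  atoms <- data.frame(
    type  = at$type,
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesy = as.character(at$elesy),
    alt   = ifelse(is.na(at$alt), "", as.character(at$alt)),
    o     = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    stringsAsFactors = FALSE
  )
  if (nrow(atoms) == 0L) stop("no atom records in '", path, "'")
  structure(list(atoms = atoms, source = path), class = "eet_structure")
}

#' @export
print.eet_structure <- function(x, ...) {
  cat("<eet_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chains [", x$source, "]\n", sep = "")
  invisible(x)
}

#' Default residue-code map for chlorophyll extraction
#'
#' Maps PDB hetero residue codes to pigment types: `CLA` is chlorophyll a;
#' `KC1`/`KC2` are chlorophyll c1/c2.
#' @return Named character vector (code -> `"CHL_A"`/`"CHL_C"`).
#' @export
default_code_map <- function() {
  c(CLA = "CHL_A", KC1 = "CHL_C", KC2 = "CHL_C")
}

.pigment_id <- function(chain, resno, resid) {
  sprintf("%s:%d:%s", chain, resno, resid)
}

#' Extract chlorophyll pigments from a structural model
#'
#' Builds one pigment per residue whose code appears in `code_map`, keeping the
#' highest-occupancy alternate location per atom (ties broken by altloc
#' identifier order). The pigment center is the Mg position, or the mean of
#' the four chlorin ring nitrogens (NA/NB/NC/ND) when Mg is absent. The Qy
#' transition axis is the unit vector between the two `axis_atoms`
#' (conventionally NB -> ND).
#'
#' @param model An `eet_structure` from [read_structure()].
#' @param code_map Named character vector, residue code -> pigment type;
#'   default [default_code_map()].
#' @param axis_atoms Length-2 atom names defining the Qy axis (from, to).
#' @param allow_missing If `TRUE`, residues lacking an axis atom are skipped
#'   with a warning instead of aborting the extraction.
#' @return A `pigment_set`: ordered list of pigments (sorted by chain, then
#'   residue number), each with `id`, `chain`, `resno`, `resid`, `type`,
#'   `atom_coords` (named n x 3 matrix, Angstrom), `center`, `qy_axis`.
#' @export
extract_pigments <- function(model, code_map = default_code_map(),
                             axis_atoms = c("NB", "ND"),
                             allow_missing = FALSE) {
  stopifnot(inherits(model, "eet_structure"), length(axis_atoms) == 2L)
  if (!"CLA" %in% names(code_map))
    stop("code_map must cover at least CLA")
  at <- model$atoms[model$atoms$resid %in% names(code_map), , drop = FALSE]
  pigments <- list()
  skipped <- character()
  if (nrow(at) > 0L) {
    key <- paste(at$chain, at$resno, at$resid, sep = "\r")
    for (k in unique(key)) {
      res <- at[key == k, , drop = FALSE]
      # altloc: keep highest occupancy per atom name, ties by altloc order
      res <- res[order(res$elety, -res$o, res$alt), , drop = FALSE]
      res <- res[!duplicated(res$elety), , drop = FALSE]
      coords <- as.matrix(res[, c("x", "y", "z")])
      rownames(coords) <- res$elety
      id <- .pigment_id(res$chain[1], res$resno[1], res$resid[1])
      if ("MG" %in% rownames(coords)) {
        center <- coords["MG", ]
      } else {
        ringN <- c("NA", "NB", "NC", "ND")
        if (!all(ringN %in% rownames(coords)))
          stop("residue ", id, " lacks both Mg and the four ring nitrogens")
        center <- colMeans(coords[ringN, , drop = FALSE])
      }
      if (!all(axis_atoms %in% rownames(coords))) {
        if (allow_missing) {
          warning("skipping ", id, ": missing Qy-axis atom(s) ",
                  paste(setdiff(axis_atoms, rownames(coords)), collapse = ","))
          skipped <- c(skipped, id)
          next
        }
        stop("residue ", id, " lacks Qy-axis atom(s) ",
             paste(setdiff(axis_atoms, rownames(coords)), collapse = ","),
             " (set allow_missing = TRUE to skip)")
      }
      ax <- coords[axis_atoms[2], ] - coords[axis_atoms[1], ]
      nrm <- sqrt(sum(ax^2))
      if (nrm == 0) stop("residue ", id, ": degenerate Qy axis")
      pigments[[id]] <- list(
        id = id, chain = res$chain[1], resno = res$resno[1],
        resid = res$resid[1], type = unname(code_map[res$resid[1]]),
        atom_coords = coords, center = unname(center),
        qy_axis = unname(ax / nrm)
      )
    }
  }
  ord <- order(vapply(pigments, `[[`, "", "chain"),
               vapply(pigments, `[[`, 0L, "resno"))
  pigment_set(pigments[ord], source = model$source,
              provenance = model$source, skipped = skipped)
}

#' Construct a pigment set
#'
#' @param pigments List of pigment records (see [extract_pigments()]).
#' @param source,provenance Labels recording where the pigments came from.
#' @param skipped Ids of residues skipped during extraction.
#' @return A `pigment_set` object.
#' @export
pigment_set <- function(pigments, source = "manual", provenance = source,
                        skipped = character()) {
  ids <- vapply(pigments, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate pigment ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(pigments) <- ids
  for (p in pigments) {
    if (!all(is.finite(p$center))) stop("non-finite center for ", p$id)
    if (abs(sqrt(sum(p$qy_axis^2)) - 1) > 1e-8)
      stop("qy_axis of ", p$id, " is not unit length")
  }
  structure(list(pigments = pigments, source = source,
                 provenance = provenance, skipped = skipped),
            class = "pigment_set")
}

#' @export
length.pigment_set <- function(x) length(x$pigments)

#' @export
print.pigment_set <- function(x, ...) {
  tt <- table(vapply(x$pigments, `[[`, "", "type"))
  cat("<pigment_set> ", length(x), " pigments (",
      paste(sprintf("%s: %d", names(tt), tt), collapse = ", "),
      ") from ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pigment_set <- function(x, ...) {
  do.call(rbind, lapply(x$pigments, function(p) {
    data.frame(id = p$id, chain = p$chain, resnum = p$resno, type = p$type,
               center_x = p$center[1], center_y = p$center[2],
               center_z = p$center[3],
               qy_x = p$qy_axis[1], qy_y = p$qy_axis[2], qy_z = p$qy_axis[3],
               domain = if (is.null(p$domain_id)) NA_character_ else p$domain_id,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write the pigment table as TSV
#' @param pigments A `pigment_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pigment_table <- function(pigments, path) {
  utils::write.table(as.data.frame(pigments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign pigments to domains (aggregates)
#'
#' Partitions a pigment set into donor/acceptor aggregates for the
#' generalized-Forster treatment. By default each chain becomes its own
#' ANTENNA domain; chains listed in `core_chains` are merged into a single
#' CORE domain (the conventional layout for an antenna ring around a
#' reaction-center core).
#'
#' @param pigments A `pigment_set`.
#' @param chain_roles Optional data frame with columns `chain`, `domain_id`,
#'   `role` (and optionally `display`); overrides the default rule.
#' @param core_chains Chains to merge into the CORE domain under the default
#'   rule.
#' @param default_rule If `FALSE` and a pigment's chain is absent from
#'   `chain_roles`, an error lists the unmapped chains.
#' @return A `domain_partition`: list with `domains` (named list of pigment id
#'   vectors), `roles` (named "CORE"/"ANTENNA"), `display` (named labels).
#' @export
assign_domains <- function(pigments, chain_roles = NULL,
                           core_chains = character(),
                           default_rule = is.null(chain_roles)) {
  stopifnot(inherits(pigments, "pigment_set"))
  chains <- vapply(pigments$pigments, `[[`, "", "chain")
  map_dom <- character(); map_role <- character(); map_disp <- character()
  if (!is.null(chain_roles)) {
    stopifnot(is.data.frame(chain_roles),
              all(c("chain", "domain_id", "role") %in% names(chain_roles)))
    map_dom[chain_roles$chain] <- chain_roles$domain_id
    map_role[chain_roles$chain] <- chain_roles$role
    map_disp[chain_roles$chain] <-
      if ("display" %in% names(chain_roles)) chain_roles$display
      else chain_roles$domain_id
  }
  unmapped <- setdiff(unique(chains), names(map_dom))
  if (length(unmapped)) {
    if (!default_rule)
      stop("chains without a domain mapping: ",
           paste(unmapped, collapse = ", "))
    for (ch in unmapped) {
      if (ch %in% core_chains) {
        map_dom[ch] <- "CORE"; map_role[ch] <- "CORE"; map_disp[ch] <- "CORE"
      } else {
        map_dom[ch] <- ch; map_role[ch] <- "ANTENNA"; map_disp[ch] <- ch
      }
    }
  }
  dom_of <- map_dom[chains]
  domains <- split(names(pigments$pigments), dom_of)
  roles <- vapply(names(domains), function(d)
    unique(map_role[map_dom == d])[1], "")
  display <- vapply(names(domains), function(d)
    unique(map_disp[map_dom == d])[1], "")
  part <- structure(list(domains = domains, roles = roles, display = display),
                    class = "domain_partition")
  validate_partition(part, pigments)
  part
}

#' Validate that a partition is exhaustive and disjoint over a pigment set
#' @param partition A `domain_partition`.
#' @param pigments The `pigment_set` it should cover.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_partition <- function(partition, pigments) {
  stopifnot(inherits(partition, "domain_partition"))
  all_ids <- unlist(partition$domains, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("partition not disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (any(lengths(partition$domains) == 0L)) stop("empty domain in partition")
  if (!setequal(all_ids, names(pigments$pigments)))
    stop("partition is not exhaustive over the pigment set")
  invisible(TRUE)
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("<domain_partition> ", length(x$domains), " domains (",
      sum(x$roles == "CORE"), " CORE, ", sum(x$roles == "ANTENNA"),
      " ANTENNA)\n", sep = "")
  invisible(x)
}

#' Pairwise center-to-center distance table
#'
#' @param pigments A `pigment_set` with at least 2 pigments.
#' @param min_separation Centers closer than this (Angstrom) trigger a
#'   degenerate-geometry error.
#' @return Symmetric matrix of distances in Angstrom, zero diagonal, pigment
#'   ids as dimnames.
#' @export
pairwise_geometry <- function(pigments, min_separation = 0.1) {
  stopifnot(inherits(pigments, "pigment_set"))
  if (length(pigments) < 2L) stop("need at least 2 pigments")
  centers <- t(vapply(pigments$pigments, `[[`, numeric(3), "center"))
  d <- as.matrix(stats::dist(centers))
  dimnames(d) <- list(names(pigments$pigments), names(pigments$pigments))
  off <- d[upper.tri(d)]
  if (any(off < min_separation))
    stop("degenerate geometry: pigment centers closer than ",
         min_separation, " Angstrom")
  d
}

#' Read a pipeline configuration file (YAML)
#'
#' Schema: top-level keys `code_map` (residue code -> pigment type) and
#' `chain_roles` (list of `{chain, domain_id, role, display}` records).
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file.
#' @return List with `code_map` (named character) and `chain_roles`
#'   (data frame or `NULL`).
#' @export
read_eet_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  code_map <- if (is.null(cfg$code_map)) default_code_map()
              else unlist(cfg$code_map)
  chain_roles <- NULL
  if (!is.null(cfg$chain_roles)) {
    chain_roles <- do.call(rbind, lapply(cfg$chain_roles, function(r)
      data.frame(chain = r$chain, domain_id = r$domain_id, role = r$role,
                 display = if (is.null(r$display)) r$domain_id else r$display,
                 stringsAsFactors = FALSE)))
  }
  list(code_map = code_map, chain_roles = chain_roles)
}
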