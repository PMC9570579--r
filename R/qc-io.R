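## qcdata v1 JSON I/O for QuantumCenter objects.
##
## Schema (all numbers in package units: kJ/mol, nm, e, e.nm):
##   species_name : string
##   total_charge : integer (e)
##   atoms        : [{label, element, position [x,y,z], is_acidic_proton}]
##   states       : [{index, energy0, atomic_charges [...]}]
##   dipoles      : [{i, j, vector [x,y,z]}]  (0-based state indices,
##                  one entry per unordered pair including i == j)

.qcFormatError <- function(field, detail) {
  stop(sprintf("qcdata format error in field '%s': %s", field, detail),
       call. = FALSE)
}

#' Read a quantum center from a qcdata v1 JSON file
#'
#' Parses and validates the package's JSON exchange format for
#' quantum-center electronic data. States are re-sorted by unperturbed
#' energy when the file lists them out of order (with a warning); all
#' class invariants (charge sums, dipole symmetry, center of mass) are
#' enforced on the returned object.
#'
#' @param path Path to a qcdata v1 JSON file.
#' @return A validated \code{\link{QuantumCenter}}.
#' @seealso \code{\link{writeQuantumCenter}}, \code{\link{readQuantumCenterTable}}
#' @export
readQuantumCenter <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("species_name", "total_charge", "atoms", "states", "dipoles"))
    if (is.null(doc[[key]])) .qcFormatError(key, "missing")

  atoms <- doc$atoms
  na <- length(atoms)
  if (na < 1L) .qcFormatError("atoms", "at least one atom required")
  lab <- character(na); ele <- character(na); acid <- logical(na)
  pos <- matrix(NA_real_, na, 3L)
  for (i in seq_len(na)) {
    a <- atoms[[i]]
    for (key in c("label", "element", "position", "is_acidic_proton"))
      if (is.null(a[[key]]))
        .qcFormatError(sprintf("atoms[%d].%s", i, key), "missing")
    if (length(a$position) != 3L)
      .qcFormatError(sprintf("atoms[%d].position", i), "must be a 3-vector")
    lab[i] <- a$label; ele[i] <- a$element
    acid[i] <- isTRUE(a$is_acidic_proton)
    pos[i, ] <- as.numeric(a$position)
  }

  states <- doc$states
  ns <- length(states)
  if (ns < 1L) .qcFormatError("states", "at least one state required")
  energies <- numeric(ns)
  charges <- matrix(NA_real_, ns, na)
  idx <- integer(ns)
  for (s in seq_len(ns)) {
    st <- states[[s]]
    for (key in c("index", "energy0", "atomic_charges"))
      if (is.null(st[[key]]))
        .qcFormatError(sprintf("states[%d].%s", s, key), "missing")
    if (length(st$atomic_charges) != na)
      .qcFormatError(sprintf("states[%d].atomic_charges", s),
                     sprintf("expected %d charges, got %d", na,
                             length(st$atomic_charges)))
    idx[s] <- as.integer(st$index)
    energies[s] <- as.numeric(st$energy0)
    charges[s, ] <- as.numeric(st$atomic_charges)
  }
  ord <- order(energies)
  if (is.unsorted(energies)) {
    warning("qcdata states listed out of energy order in '", path,
            "'; re-sorted ascending", call. = FALSE)
  }
  perm <- idx[ord] + 1L  # original 0-based index -> new position lookup
  rank <- integer(ns); rank[perm] <- seq_len(ns)
  energies <- energies[ord]
  charges <- charges[ord, , drop = FALSE]

  dipoles <- array(NA_real_, c(ns, ns, 3L))
  for (e in doc$dipoles) {
    for (key in c("i", "j", "vector"))
      if (is.null(e[[key]])) .qcFormatError("dipoles", paste(key, "missing"))
    if (length(e$vector) != 3L)
      .qcFormatError("dipoles.vector", "must be a 3-vector")
    i <- rank[as.integer(e$i) + 1L]
    j <- rank[as.integer(e$j) + 1L]
    if (is.na(i) || is.na(j))
      .qcFormatError("dipoles", sprintf("state index (%s,%s) out of range",
                                        e$i, e$j))
    v <- as.numeric(e$vector)
    dipoles[i, j, ] <- v
    dipoles[j, i, ] <- v
  }
  if (anyNA(dipoles))
    .qcFormatError("dipoles", "must cover all state pairs")

  total <- as.integer(doc$total_charge)
  csum <- rowSums(charges)
  if (any(abs(csum - total) > 1e-6))
    stop(sprintf(
      "qcdata validation error: state charges sum to %.6f but total_charge is %d",
      csum[which.max(abs(csum - total))], total), call. = FALSE)

  QuantumCenter(
    speciesName = doc$species_name, totalCharge = total,
    atoms = data.frame(label = lab, element = ele, is_acidic_proton = acid,
                       stringsAsFactors = FALSE),
    positions = pos, energies = energies, charges = charges,
    dipoles = dipoles)
}

#' Write a quantum center to a qcdata v1 JSON file
#'
#' The serialization is lossless at full double precision:
#' \code{readQuantumCenter(writeQuantumCenter(qc, path))} reproduces
#' \code{qc} field-wise.
#'
#' @param qc A \code{\link{QuantumCenter}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeQuantumCenter <- function(qc, path) {
  validObject(qc)
  ns <- nStates(qc)
  atoms <- lapply(seq_len(nAtoms(qc)), function(i) list(
    label = qc@atoms$label[i], element = qc@atoms$element[i],
    position = qc@positions[i, ],
    is_acidic_proton = qc@atoms$is_acidic_proton[i]))
  states <- lapply(seq_len(ns), function(s) list(
    index = s - 1L, energy0 = qc@energies[s],
    atomic_charges = qc@charges[s, ]))
  dip <- list()
  for (i in seq_len(ns)) for (j in i:ns)
    dip[[length(dip) + 1L]] <- list(i = i - 1L, j = j - 1L,
                                    vector = qc@dipoles[i, j, ])
  doc <- list(species_name = qc@speciesName,
              total_charge = qc@totalCharge,
              atoms = atoms, states = states, dipoles = dip)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to '", path, "': ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), con)
  invisible(path)
}

#' Import a quantum center from a plain-text block table
#'
#' Hand-editable alternative to the JSON format, intended for small
#' fixtures. The file has a header section and one \code{state} block per
#' electronic state:
#' \preformatted{
#' species <name>
#' total_charge <q>
#' atom <label> <element> <x> <y> <z> <0|1>   # one line per atom
#' state <index> <energy0> <q1> <q2> ... <qN>
#' dipole <i> <j> <x> <y> <z>
#' }
#' Blank lines and lines starting with \code{#} are ignored.
#'
#' @param path Path to the table file.
#' @return A validated \code{\link{QuantumCenter}}.
#' @export
readQuantumCenterTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  species <- NULL; total <- NULL
  lab <- character(); ele <- character(); acid <- logical()
  pos <- NULL; states <- list(); dip <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]
    if (key == "species") species <- tok[2]
    else if (key == "total_charge") total <- as.integer(tok[2])
    else if (key == "atom") {
      lab <- c(lab, tok[2]); ele <- c(ele, tok[3])
      pos <- rbind(pos, as.numeric(tok[4:6]))
      acid <- c(acid, tok[7] == "1")
    } else if (key == "state") {
      states[[length(states) + 1L]] <- list(
        index = as.integer(tok[2]), energy0 = as.numeric(tok[3]),
        atomic_charges = as.numeric(tok[-(1:3)]))
    } else if (key == "dipole") {
      dip[[length(dip) + 1L]] <- list(i = as.integer(tok[2]),
                                      j = as.integer(tok[3]),
                                      vector = as.numeric(tok[4:6]))
    } else .qcFormatError(key, "unknown record type")
  }
  if (is.null(species) || is.null(total))
    .qcFormatError("header", "species and total_charge required")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  doc <- list(
    species_name = species, total_charge = total,
    atoms = lapply(seq_along(lab), function(i) list(
      label = lab[i], element = ele[i], position = pos[i, ],
      is_acidic_proton = acid[i])),
    states = states, dipoles = dip)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17)), tmp)
  readQuantumCenter(tmp)
}
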