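#' DNA unwrapping footprint across a model population
#'
#' Assigns each base pair of the template a binary histone-contact score in
#' each model and averages across the population, giving the probability of
#' finding each base pair in contact with an octamer surface.
#'
#' In `path8A` mode (the default, and the only mode available for
#' trace-level models) a base pair scores 1 when it belongs to a placement's
#' detected wrapped interval, i.e. when it lies on the 8 A-criterion overlap
#' with the ideal superhelical path. In `atomic4A` mode, available for
#' models carrying an `atoms` block of atomic coordinates, a base pair
#' scores 1 when any of its atoms falls within 4 A of any histone atom.
#'
#' @param models list of `nuca_model` sharing one template.
#' @param mode `"path8A"` or `"atomic4A"`.
#' @return list of class `nuca_footprint`: `prob` (length `total_bp`, values
#'   in [0, 1]), `n_models`, `mode`.
#' @export
unwrap_footprint <- function(models, mode = c("path8A", "atomic4A")) {
  mode <- match.arg(mode)
  if (!length(models)) stop("empty model list")
  tot <- vapply(models, function(m) m$template$total_bp, integer(1))
  if (length(unique(tot)) != 1L)
    stop("models must share a template")
  n_bp <- tot[1]
  acc <- numeric(n_bp)
  for (m in models) {
    score <- numeric(n_bp)
    if (mode == "path8A") {
      for (p in m$placements) {
        if (p$absent) next
        score[(p$wrap_interval[1] + 1L):p$wrap_interval[2]] <- 1
      }
    } else {
      at <- m$atoms
      if (is.null(at))
        stop("atomic4A mode requires models with an 'atoms' block")
      score <- atomic_contact_scores(at, n_bp)
    }
    acc <- acc + score
  }
  structure(list(prob = acc / length(models), n_models = length(models),
                 mode = mode), class = "nuca_footprint")
}

# Any-atom within 4 A of any histone atom, per bp.
atomic_contact_scores <- function(atoms, n_bp, cutoff = 4) {
  score <- numeric(n_bp)
  hx <- atoms$histone_xyz
  for (bp in unique(atoms$dna_bp)) {
    px <- atoms$dna_xyz[atoms$dna_bp == bp, , drop = FALSE]
    if (min(cross_dist2(px, hx)) < cutoff^2) score[bp + 1L] <- 1
  }
  score
}

#' Read an all-atom PDB into the atomic-contact representation
#'
#' Maps chains to roles ("dna" or "histone") through a YAML configuration
#' (`chains: {I: dna, J: dna, A: histone, ...}`; optionally
#' `bp_offset: <int>` added to DNA residue numbers to give 0-based bp
#' indices). DNA base-pair indices are taken from residue numbers.
#'
#' @param pdb_path path to a PDB file (read with bio3d).
#' @param chain_map_yaml path to the YAML chain-role map.
#' @return an `atoms` block: list(dna_bp, dna_xyz, histone_xyz).
#' @export
read_atomic_pdb <- function(pdb_path, chain_map_yaml) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("the 'bio3d' package is required for atomic PDB input")
  cfg <- yaml::read_yaml(chain_map_yaml)
  roles <- unlist(cfg$chains)
  off <- cfg$bp_offset %||% 0L
  pdb <- bio3d::read.pdb(pdb_path)
  a <- pdb$atom
  role <- roles[a$chain]
  xyz <- cbind(a$x, a$y, a$z)
  dna <- which(role == "dna")
  his <- which(role == "histone")
  if (!length(dna) || !length(his))
    stop("chain map must assign at least one dna and one histone chain")
  list(dna_bp = as.integer(a$resno[dna]) + as.integer(off),
       dna_xyz = xyz[dna, , drop = FALSE],
       histone_xyz = xyz[his, , drop = FALSE])
}
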