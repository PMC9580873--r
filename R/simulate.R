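#' Planted identity-pair coupling
#'
#' Describes one coupling to plant in a synthetic alignment: at positions
#' `(i, j)`, with some mixture weight `lambda`, a sequence carries the
#' identities `(a, b)` jointly; otherwise both columns draw independently
#' from their background profiles. Writing `p = f_a`, `q = f_b` for the
#' background frequencies, the realized (generative) residual is
#'
#'   `r(lambda) = lambda (1 - lambda) (1 - p) (1 - q)`
#'
#' since the mixed joint is `lambda + (1-lambda) p q` and the mixed
#' marginals are `lambda + (1-lambda) p` and `lambda + (1-lambda) q`.
#' `lambda` is solved on the increasing branch `[0, 1/2]` so that
#' `r(lambda) = rho`; the achievable maximum is `0.25 (1-p)(1-q)` at
#' `lambda = 1/2`, and a `rho` beyond it raises a feasibility error that
#' states the maximum.
#'
#' @param i,j alignment positions (`i < j`, 1-based).
#' @param a,b residue identities to couple.
#' @param rho target residual in `(0, 0.25]`.
#' @return A list of class `coev_coupling`.
#' @export
planted_coupling <- function(i, j, a, b, rho) {
  if (i >= j) stop("need i < j", call. = FALSE)
  if (!a %in% AA20 || !b %in% AA20) {
    stop("coupled identities must be amino acids (gap couplings are not planted)",
         call. = FALSE)
  }
  if (rho <= 0 || rho > 0.25) stop("rho must lie in (0, 0.25]", call. = FALSE)
  structure(list(i = as.integer(i), j = as.integer(j), a = a, b = b,
                 rho = rho), class = "coev_coupling")
}

## realized residual of the coupling mixture at weight lambda
coupling_residual <- function(lambda, p, q) {
  joint <- lambda + (1 - lambda) * p * q
  ma <- lambda + (1 - lambda) * p
  mb <- lambda + (1 - lambda) * q
  joint - ma * mb
}

## solve coupling_residual(lambda) == rho on [0, 1/2]
solve_lambda <- function(rho, p, q) {
  rmax <- 0.25 * (1 - p) * (1 - q)
  if (rho > rmax + 1e-12) {
    stop(sprintf(paste0("target residual rho = %.4f is infeasible for ",
                        "background frequencies f_a = %.4f, f_b = %.4f; ",
                        "the achievable maximum is %.4f (at lambda = 1/2)"),
                 rho, p, q, rmax), call. = FALSE)
  }
  if (abs(rho - rmax) <= 1e-12) return(0.5)
  lam <- stats::uniroot(function(l) coupling_residual(l, p, q) - rho,
                        lower = 0, upper = 0.5, tol = 1e-14)$root
  stopifnot(abs(coupling_residual(lam, p, q) - rho) <= 1e-9)
  lam
}

#' Specification of a synthetic alignment
#'
#' @param n_sequences number of rows to simulate.
#' @param length number of columns `L`.
#' @param concentration symmetric Dirichlet concentration for the
#'   per-column background profiles; the default 0.5 gives moderately
#'   peaked profiles resembling conserved-ish family columns, larger
#'   values give flatter ("uniform-ish") columns.
#' @param couplings list of [planted_coupling()] objects; their position
#'   pairs must be disjoint.
#' @param gap_fraction fraction of cells replaced by gaps uniformly at
#'   random (default 0; used to exercise gap handling).
#' @param seed mandatory integer seed.
#' @return A list of class `coev_synth_spec`.
#' @export
synthetic_spec <- function(n_sequences, length, concentration = 0.5,
                           couplings = list(), gap_fraction = 0, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for synthetic specs", call. = FALSE)
  }
  pos <- unlist(lapply(couplings, function(cp) c(cp$i, cp$j)))
  if (anyDuplicated(pos)) {
    stop("coupled position pairs must be disjoint", call. = FALSE)
  }
  if (length(pos) > 0 && max(pos) > length) {
    stop("coupling positions exceed alignment length", call. = FALSE)
  }
  if (gap_fraction < 0 || gap_fraction >= 1) {
    stop("gap_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 concentration = concentration,
                 couplings = couplings,
                 gap_fraction = gap_fraction,
                 seed = as.integer(seed)),
            class = "coev_synth_spec")
}

#' Generate a synthetic alignment with planted couplings
#'
#' Per-column background profiles over the 20 amino acids are sampled once
#' from a symmetric Dirichlet; each sequence then draws every column
#' independently from its profile. For each planted coupling, a sequence
#' is "coupled" with probability `lambda` (solved from the target residual
#' `rho`, see [planted_coupling()]), in which case positions `(i, j)` are
#' overwritten with the identities `(a, b)`; otherwise both columns keep
#' their independent draws. The realized population residual at
#' `(i, a, j, b)` therefore converges to `rho` as the number of sequences
#' grows.
#'
#' @param spec a [synthetic_spec()].
#' @return A `coev_alignment` with attribute `planted`: a data frame of
#'   the couplings with their background frequencies and solved `lambda`.
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "coev_synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_sequences
    L <- spec$length
    ## column profiles: symmetric Dirichlet via normalized gammas
    profiles <- matrix(stats::rgamma(20L * L, shape = spec$concentration),
                       nrow = 20L, ncol = L)
    profiles <- sweep(profiles, 2L, colSums(profiles), "/")
    rownames(profiles) <- AA20
    ## solve mixture weights before any sequence sampling so infeasible
    ## targets fail fast
    planted <- NULL
    if (length(spec$couplings) > 0L) {
      planted <- do.call(rbind, lapply(spec$couplings, function(cp) {
        p <- profiles[cp$a, cp$i]
        q <- profiles[cp$b, cp$j]
        data.frame(i = cp$i, j = cp$j, a = cp$a, b = cp$b, rho = cp$rho,
                   f_a = p, f_b = q,
                   lambda = solve_lambda(cp$rho, p, q),
                   stringsAsFactors = FALSE)
      }))
    }
    mat <- matrix("", nrow = n, ncol = L)
    for (k in seq_len(L)) {
      mat[, k] <- sample(AA20, n, replace = TRUE, prob = profiles[, k])
    }
    if (!is.null(planted)) {
      for (r in seq_len(nrow(planted))) {
        coupled <- stats::runif(n) < planted$lambda[r]
        mat[coupled, planted$i[r]] <- planted$a[r]
        mat[coupled, planted$j[r]] <- planted$b[r]
      }
    }
    if (spec$gap_fraction > 0) {
      gaps <- stats::runif(n * L) < spec$gap_fraction
      mat[matrix(gaps, nrow = n)] <- "-"
    }
    aln <- coev_alignment(sprintf("synth%04d", seq_len(n)),
                          apply(mat, 1L, paste, collapse = ""))
    attr(aln, "planted") <- planted
    attr(aln, "profiles") <- profiles
    aln
  })
}

#' Ideal alpha-helix alpha-carbon trace
#'
#' Generates an idealized helical backbone: alpha-carbon radius 2.3 Å,
#' rise 1.5 Å per residue, twist 100 degrees per residue. Inter-residue
#' distances then follow the closed form
#' `d(s) = sqrt((2 r sin(s * twist/2))^2 + (rise * s)^2)`, which makes the
#' helix a self-checking fixture for distance baselines (`d(1)` is about
#' 3.83 Å).
#'
#' @param n_res number of residues (`>= 2`).
#' @param radius,rise,twist helix parameters (Å, Å/residue, degrees/residue).
#' @param path optional path; when given, the trace is also written as a
#'   single-chain PDB file.
#' @return A `coev_structure` (alpha-carbon scheme, chain `"A"`, all
#'   residues alanine).
#' @export
generate_helix <- function(n_res, radius = 2.3, rise = 1.5, twist = 100,
                           path = NULL) {
  if (n_res < 2L) stop("need n_res >= 2", call. = FALSE)
  k <- seq_len(n_res) - 1L
  theta <- twist * pi / 180 * k
  xyz <- cbind(x = radius * cos(theta), y = radius * sin(theta),
               z = rise * k)
  model <- toy_structure(xyz)
  if (!is.null(path)) write_structure_pdb(model, path)
  model
}

#' Closed-form helix distance
#'
#' @param s sequential separation (vectorized; `d(0) = 0`).
#' @param radius,rise,twist helix parameters as in [generate_helix()].
#' @return Distances in Å.
#' @export
helix_distance <- function(s, radius = 2.3, rise = 1.5, twist = 100) {
  delta <- twist * pi / 180 * s
  sqrt((2 * radius * sin(delta / 2))^2 + (rise * s)^2)
}

#' Seeded random-chain backbone
#'
#' A random walk with fixed step length `bond` (default 3.8 Å, the
#' consecutive alpha-carbon distance of an extended chain). An optional
#' excluded-volume constraint rejects steps landing within
#' `min_separation` of any earlier non-bonded residue; placement failure
#' after `max_retries` rejections raises an error suggesting a looser
#' constraint.
#'
#' @param n_res number of residues (`>= 2`).
#' @param bond step length in Å (`> 0`).
#' @param seed mandatory integer seed.
#' @param min_separation minimum non-bonded inter-residue distance (0
#'   disables the constraint).
#' @param max_retries rejection budget per step.
#' @param path optional path for a PDB copy.
#' @return A `coev_structure`.
#' @export
generate_chain <- function(n_res, bond = 3.8, seed, min_separation = 0,
                           max_retries = 200L, path = NULL) {
  if (n_res < 2L) stop("need n_res >= 2", call. = FALSE)
  if (bond <= 0) stop("bond length must be positive", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  xyz <- with_seed(seed, {
    m <- matrix(0, nrow = n_res, ncol = 3L)
    for (k in 2:n_res) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        step <- stats::rnorm(3L)
        step <- step / sqrt(sum(step^2)) * bond
        cand <- m[k - 1L, ] + step
        if (min_separation > 0 && k > 2L) {
          prev <- m[seq_len(k - 2L), , drop = FALSE]
          d2 <- rowSums((prev - matrix(cand, nrow(prev), 3L, byrow = TRUE))^2)
          if (any(d2 < min_separation^2)) next
        }
        m[k, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("excluded-volume placement failed at residue ", k,
             " after ", max_retries, " retries; lower min_separation",
             call. = FALSE)
      }
    }
    m
  })
  colnames(xyz) <- c("x", "y", "z")
  model <- toy_structure(xyz)
  if (!is.null(path)) write_structure_pdb(model, path)
  model
}

## wrap a coordinate matrix as a coev_structure (poly-alanine CA trace)
toy_structure <- function(xyz, chain = "A") {
  n <- nrow(xyz)
  residues <- data.frame(resno = seq_len(n), insert = "", resid = "ALA",
                         aa = "A", x = xyz[, 1L], y = xyz[, 2L],
                         z = xyz[, 3L], missing = FALSE,
                         stringsAsFactors = FALSE)
  structure(list(chain = chain, atom_scheme = "ca", residues = residues,
                 sequence = paste(rep("A", n), collapse = "")),
            class = "coev_structure")
}

#' Write a residue model as a single-chain PDB file
#'
#' One atom per residue (the representative atom, written as `CA`),
#' standard fixed-width ATOM records via bio3d.
#'
#' @param model a `coev_structure` (residues with coordinates only).
#' @param path output path.
#' @param chain chain identifier for the written file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path, chain = model$chain) {
  stopifnot(inherits(model, "coev_structure"))
  res <- model$residues[!model$residues$missing, , drop = FALSE]
  if (nrow(res) == 0L) stop("model has no placed residues", call. = FALSE)
  xyz <- as.vector(t(as.matrix(res[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = res$resno, resid = res$resid,
                   elety = rep("CA", nrow(res)),
                   chain = rep(chain, nrow(res)))
  invisible(path)
}
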