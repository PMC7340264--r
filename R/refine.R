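## Refinement backend contract and the built-in toy least-squares engine.
##
## The toy engine minimises sum_work (|Fo| - k |Fc|)^2 over a global scale
## k (closed form each cycle), a global additive ADP shift, and optionally
## the atomic coordinates, by damped Gauss-Newton with step halving. It is
## a deterministic desk-scale stand-in for a full refinement program and
## honours the same contract: free-flagged reflections of the active free
## set never enter the minimised target, and the result carries Fc for all
## reflections (work and free) to the cutoff.

## Observed amplitudes of a merged set: |Fo|, or sqrt(max(I,0)) for
## intensity data (no French-Wilson treatment; documented).
obsAmplitudes <- function(merged) {
  if (merged@kind == "F") merged@value else sqrt(pmax(merged@value, 0))
}

## A, B parts (real/imag) of Fc for given atoms over precomputed geometry.
.fcParts <- function(atoms, hkl, d) {
  phase <- 2 * pi * (hkl %*% t(as.matrix(atoms[, c("x", "y", "z")])))
  f <- exp(outer(-1 / (4 * d^2), atoms$b)) *
    rep(atoms$occ * atoms$zeff, each = nrow(hkl))
  list(re = rowSums(f * cos(phase)), im = rowSums(f * sin(phase)),
       f = f, phase = phase)
}

#' Refine a model against merged data (backend contract)
#'
#' Dispatches to the selected backend. Contract: the data are truncated to
#' `d >= dCutoff`; reflections whose free flag equals `freeSet` are
#' excluded from the minimised target; the result carries calculated
#' structure factors for all reflections (work and free) to the cutoff;
#' output is deterministic for fixed inputs.
#'
#' @param model Starting [AtomicModel-class] (cell must match the data).
#' @param merged A [MergedSet-class].
#' @param dCutoff Refinement resolution cutoff (Angstrom).
#' @param nCycles Cycle budget (default 20).
#' @param freeSet Free-flag value excluded from the target (default 0).
#' @param backend "toy" or "external".
#' @param ... Backend options: `refineCoords` (toy, default TRUE),
#'   `template`/`workdir` (external).
#' @return A [RefinementResult-class].
#' @export
refineModel <- function(model, merged, dCutoff, nCycles = 20L, freeSet = 0L,
                        backend = c("toy", "external"), ...) {
  backend <- match.arg(backend)
  if (backend == "toy") toyRefine(model, merged, dCutoff, nCycles, freeSet, ...)
  else externalRefine(model, merged, dCutoff, nCycles, freeSet, ...)
}

#' Built-in toy least-squares refinement engine
#'
#' Implements the backend contract with an amplitude least-squares target:
#' each cycle fits the global scale in closed form, then takes a damped
#' Gauss-Newton step in the global ADP shift and (optionally) all
#' fractional coordinates, halving the step until the working residual
#' does not increase. The per-cycle working residual trace is
#' non-increasing by construction. A singular normal matrix triggers a
#' scale+ADP-only cycle, recorded in the result's note.
#'
#' @inheritParams refineModel
#' @param refineCoords Refine atomic coordinates as well as the global ADP
#'   shift (default TRUE).
#' @param damping Initial Levenberg-Marquardt damping (relative to the
#'   normal-matrix diagonal; adapted each cycle; default 1e-6).
#' @param convergence Relative working-residual improvement below which
#'   refinement stops before exhausting the cycle budget (default 1e-9).
#' @return A [RefinementResult-class].
#' @export
toyRefine <- function(model, merged, dCutoff, nCycles = 20L, freeSet = 0L,
                      refineCoords = TRUE, damping = 1e-6, convergence = 1e-9) {
  if (max(abs(cellParameters(model@cell) - cellParameters(merged@cell))) > 1e-3)
    stop("model cell does not match data cell")
  data <- selectResolution(merged, dCutoff)
  if (nReflections(data) == 0) stop("no reflections at this cutoff")
  work <- data@flag != freeSet
  if (!any(work)) stop("empty work set: all reflections carry the free flag")
  fo <- obsAmplitudes(data)[work]
  hklW <- data@hkl[work, , drop = FALSE]
  dW <- dSpacing(data@cell, hklW)
  atoms <- model@atoms
  note <- character(0)

  evalState <- function(atoms) {
    p <- .fcParts(atoms, hklW, dW)
    fc <- sqrt(p$re^2 + p$im^2)
    k <- sum(fo * fc) / sum(fc^2)
    list(parts = p, fc = fc, k = k, rss = sum((fo - k * fc)^2))
  }

  st <- evalState(atoms)
  trace <- st$rss
  cyc <- 0L
  nAt <- nrow(atoms)
  lambda <- damping  # adaptive Levenberg-Marquardt damping
  while (cyc < nCycles) {
    cyc <- cyc + 1L
    fcAbs <- pmax(st$fc, 1e-12)
    ## Jacobian of k|Fc| w.r.t. (dB, coords): d|Fc|/dB_shift = -|Fc|/(4 d^2)
    jB <- st$k * (-fcAbs / (4 * dW^2))
    if (refineCoords) {
      p <- st$parts
      ## d|Fc|/dx_{j,axis} = 2 pi h_axis f_j (B cos(phi_j) - A sin(phi_j)) / |Fc|
      common <- p$f * (st$parts$im / fcAbs * cos(p$phase) -
                       st$parts$re / fcAbs * sin(p$phase))
      jX <- st$k * 2 * pi * cbind(hklW[, 1] * common, hklW[, 2] * common,
                                  hklW[, 3] * common)
      J <- cbind(jB, jX)
    } else J <- cbind(jB)
    r <- fo - st$k * fcAbs
    ntm0 <- crossprod(J)
    g <- crossprod(J, r)
    dg <- pmax(diag(ntm0), 1e-12 * mean(diag(ntm0)))
    accepted <- FALSE
    for (h in 1:12) {
      ntm <- ntm0
      diag(ntm) <- diag(ntm0) + lambda * dg
      delta <- tryCatch(solve(ntm, g), error = function(e) NULL)
      if (is.null(delta) || anyNA(delta)) {
        note <- c(note, sprintf("cycle %d: singular normal matrix, scale+ADP-only step", cyc))
        delta <- matrix(c(sum(jB * r) / (sum(jB^2) * (1 + lambda)),
                          rep(0, if (refineCoords) 3 * nAt else 0)))
      }
      dB <- delta[1]
      ## keep all B factors positive
      if (min(atoms$b) + dB <= 0.01) dB <- 0.01 - min(atoms$b) + 1e-9
      cand <- atoms
      cand$b <- cand$b + dB
      if (refineCoords && length(delta) > 1) {
        dx <- matrix(delta[-1], ncol = 3)
        cand$x <- cand$x + dx[, 1]; cand$y <- cand$y + dx[, 2]; cand$z <- cand$z + dx[, 3]
      }
      stNew <- evalState(cand)
      if (stNew$rss < st$rss) {
        atoms <- cand; st <- stNew; accepted <- TRUE
        lambda <- max(lambda * 0.3, 1e-12)
        break
      }
      lambda <- lambda * 8
    }
    trace <- c(trace, st$rss)
    if (!accepted) break
    if ((trace[length(trace) - 1L] - st$rss) <=
        convergence * max(st$rss, 1e-300)) break
  }

  refined <- new("AtomicModel", cell = model@cell, atoms = atoms,
                 label = paste0(model@label, sprintf("@%.3gA", dCutoff)))
  calc <- calcStructureFactors(refined, data@hkl, dMin = dCutoff)
  new("RefinementResult", model = refined, calc = calc, trace = trace,
      scale = st$k, cutoff = dCutoff, cycles = cyc,
      note = paste(note, collapse = "; "))
}

#' External refinement backend adapter
#'
#' Runs a user-supplied shell command template containing the placeholders
#' `{model_in}`, `{hkl_in}`, `{d_cutoff}`, `{model_out}` and `{fc_out}`,
#' then parses the refined PDB model and the calculated-structure-factor
#' text file (format of [writeCalc()]) into a [RefinementResult-class].
#' The template is validated before execution; a nonzero exit status or
#' missing output file raises an error naming the captured log.
#'
#' @inheritParams refineModel
#' @param template Command template string with the five placeholders.
#' @param workdir Directory for exchange files (default a fresh tempdir).
#' @return A [RefinementResult-class].
#' @export
externalRefine <- function(model, merged, dCutoff, nCycles = 20L, freeSet = 0L,
                           template, workdir = tempfile("xrefine")) {
  need <- c("{model_in}", "{hkl_in}", "{d_cutoff}", "{model_out}", "{fc_out}")
  miss <- need[!vapply(need, function(p) grepl(p, template, fixed = TRUE), logical(1))]
  if (length(miss))
    stop("template is missing placeholder(s): ", paste(miss, collapse = ", "))
  left <- regmatches(template, gregexpr("\\{[a-z_]+\\}", template))[[1]]
  bad <- setdiff(left, need)
  if (length(bad))
    stop("template has unknown placeholder(s): ", paste(bad, collapse = ", "))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  fin <- list(model_in = file.path(workdir, "model_in.pdb"),
              hkl_in = file.path(workdir, "data.hkl"),
              model_out = file.path(workdir, "model_out.pdb"),
              fc_out = file.path(workdir, "fc_out.txt"))
  writePDB(model, fin$model_in)
  writeMerged(selectResolution(merged, dCutoff), fin$hkl_in)
  cmd <- template
  subs <- c(fin, list(d_cutoff = sprintf("%.6g", dCutoff)))
  for (nm in names(subs))
    cmd <- gsub(paste0("{", nm, "}"), subs[[nm]], cmd, fixed = TRUE)
  log <- file.path(workdir, "backend.log")
  status <- suppressWarnings(system(paste(cmd, ">", shQuote(log), "2>&1")))
  if (status != 0)
    stop("external backend exited with status ", status, "; log: ", log)
  if (!file.exists(fin$model_out) || !file.exists(fin$fc_out))
    stop("external backend did not produce its output files; log: ", log)
  refined <- readPDB(fin$model_out, label = paste0(model@label, "+external"))
  calc <- readCalc(fin$fc_out)
  data <- selectResolution(merged, dCutoff)
  work <- data@flag != freeSet
  fo <- obsAmplitudes(data)[work]
  fcAll <- Mod(calc@fc)[match(friedelKey(data@hkl), friedelKey(calc@hkl))]
  if (anyNA(fcAll)) stop("external Fc file does not cover all reflections at the cutoff")
  k <- sum(fo * fcAll[work]) / sum(fcAll[work]^2)
  new("RefinementResult", model = refined, calc = calc,
      trace = sum((fo - k * fcAll[work])^2), scale = k, cutoff = dCutoff,
      cycles = as.integer(nCycles), note = paste("external:", cmd))
}
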