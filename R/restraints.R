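# Restraint generation: enumerate hydrogen-group pairs under a distance
# cutoff and assign each pair an equilibrium distance, either by r-6
# summation over all member hydrogen pairs (mimicking NOE intensity
# averaging over equivalent hydrogens) or by the shortest member pair.

#' Effective distance by r-6 summation
#'
#' Returns `(sum_i r_i^-6)^(-1/6)` over the member hydrogen-hydrogen
#' distances of a group pair. Always less than or equal to the minimum member
#' distance, with equality only for a single member.
#'
#' @param memberDistances positive distances in Angstrom (non-empty).
#' @return effective distance in Angstrom.
#' @examples
#' r6EffectiveDistance(c(3, 6))      # 2.9922
#' r6EffectiveDistance(rep(4, 6))    # 4 * 6^(-1/6)
#' @export
r6EffectiveDistance <- function(memberDistances) {
  if (length(memberDistances) == 0L) stop("empty distance list")
  if (any(memberDistances <= 0)) stop("distances must be positive")
  sum(memberDistances^-6)^(-1 / 6)
}

#' Effective distance by the shortest member pair
#'
#' @param memberDistances distances in Angstrom (non-empty).
#' @return the minimum member distance.
#' @export
shortestEffectiveDistance <- function(memberDistances) {
  if (length(memberDistances) == 0L) stop("empty distance list")
  min(memberDistances)
}

# 1-2 / 1-3 heavy-atom relation matrix used by the "bonded" exclusion policy
.heavy_13 <- function(xyz, heavyIdx) {
  hx <- xyz[heavyIdx, , drop = FALSE]
  d <- .cdist(hx, hx)
  adj <- d > 0 & d <= 1.9
  rel <- adj | (adj %*% adj > 0)
  diag(rel) <- TRUE
  rel
}

#' Enumerate hydrogen-group pairs under a cutoff
#'
#' A pair of distinct groups qualifies when at least one member
#' hydrogen-hydrogen distance is strictly below `cutoff`; all member
#' distances are retained for the qualifying pair. Exclusion policies:
#' "none", "same-heavy" (drop pairs of groups sharing one heavy atom;
#' default) and "bonded" (additionally drop pairs whose heavy atoms are 1-2
#' or 1-3 bonded).
#'
#' @param structure a [StructureModel-class].
#' @param groups [HydrogenGroups-class] computed on the same model.
#' @param cutoff pair-selection cutoff in Angstrom (> 0), default 7.
#' @param exclusion "same-heavy" (default), "none" or "bonded".
#' @param model model index (default the groups' model).
#' @param memberFilter drop individual member distances at or beyond the
#'   cutoff instead of keeping every member of a qualifying pair? Default
#'   FALSE (members beyond the cutoff still enter the r6 sum).
#' @return list with `pairs` (data.frame `ga`, `gb`) and `members`
#'   (data.frame `pair`, `ai`, `bi`, `r`).
#' @export
enumeratePairs <- function(structure, groups, cutoff = 7.0,
                           exclusion = c("same-heavy", "none", "bonded"),
                           model = groups@model, memberFilter = FALSE) {
  exclusion <- match.arg(exclusion)
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- atomTable(structure, model)
  xyz <- cbind(a$x, a$y, a$z)
  ng <- length(groups)
  empty <- list(pairs = data.frame(ga = integer(), gb = integer()),
                members = data.frame(pair = integer(), ai = integer(),
                                     bi = integer(), r = numeric()))
  if (ng < 2L) return(empty)

  hAll <- unlist(groups@hydrogens)
  gidAll <- rep.int(seq_len(ng), lengths(groups@hydrogens))
  D <- .cdist(xyz[hAll, , drop = FALSE], xyz[hAll, , drop = FALSE])
  ut <- which(upper.tri(D), arr.ind = TRUE)
  ia <- ut[, 1]; ib <- ut[, 2]
  ga <- gidAll[ia]; gb <- gidAll[ib]
  keep <- ga != gb
  ia <- ia[keep]; ib <- ib[keep]
  ga <- ga[keep]; gb <- gb[keep]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp

  if (exclusion != "none") {
    hv <- groups@heavy
    sameHeavy <- !is.na(hv[ga]) & !is.na(hv[gb]) & hv[ga] == hv[gb]
    drop <- sameHeavy
    if (exclusion == "bonded") {
      heavyIdx <- which(a$element != "H")
      rel <- .heavy_13(xyz, heavyIdx)
      pos <- match(hv, heavyIdx)
      ok <- !is.na(pos[ga]) & !is.na(pos[gb])
      drop[ok] <- drop[ok] | rel[cbind(pos[ga][ok], pos[gb][ok])]
    }
    ia <- ia[!drop]; ib <- ib[!drop]
    ga <- ga[!drop]; gb <- gb[!drop]
  }
  if (length(ga) == 0L) return(empty)

  r <- sqrt(rowSums((xyz[hAll[ia], , drop = FALSE] -
                       xyz[hAll[ib], , drop = FALSE])^2))
  pairKey <- ga * (ng + 1) + gb
  qualifies <- tapply(r < cutoff, pairKey, any)
  goodKeys <- as.numeric(names(qualifies))[unlist(qualifies)]
  keep <- pairKey %in% goodKeys
  if (memberFilter) keep <- keep & r < cutoff
  if (!any(keep)) return(empty)
  ia <- ia[keep]; ib <- ib[keep]; ga <- ga[keep]; gb <- gb[keep]
  r <- r[keep]; pairKey <- pairKey[keep]

  o <- order(ga, gb)
  ia <- ia[o]; ib <- ib[o]; ga <- ga[o]; gb <- gb[o]; r <- r[o]
  pairKey <- pairKey[o]
  pid <- match(pairKey, unique(pairKey))
  first <- !duplicated(pid)
  list(pairs = data.frame(ga = ga[first], gb = gb[first]),
       members = data.frame(pair = pid, ai = hAll[ia], bi = hAll[ib], r = r))
}

#' Build a restraint set from a structure's own hydrogen distances
#'
#' Runs hydrogen grouping and pair enumeration on one model and assigns each
#' surviving group pair an equilibrium distance by the chosen method.
#'
#' @param structure a [StructureModel-class] with hydrogens.
#' @param method "shortest" (default) or "r6".
#' @param cutoff pair-selection cutoff in Angstrom (default 7).
#' @param exclusion exclusion policy, see [enumeratePairs()].
#' @param model source model index (default 1).
#' @param groups optional precomputed [HydrogenGroups-class].
#' @return a [RestraintSet-class]; empty (with a warning) when no hydrogen
#'   pair falls under the cutoff.
#' @export
buildRestraints <- function(structure, method = c("shortest", "r6"),
                            cutoff = 7.0, exclusion = "same-heavy",
                            model = 1L, groups = NULL) {
  method <- match.arg(method)
  if (is.null(groups))
    groups <- findHydrogenGroups(structure, model = model)
  pe <- enumeratePairs(structure, groups, cutoff = cutoff,
                       exclusion = exclusion, model = model)
  if (nrow(pe$pairs) == 0L) {
    if (length(groups) > 0L) warning("no hydrogen pairs under the cutoff")
    return(new("RestraintSet",
               restraints = data.frame(ga = integer(), gb = integer(),
                                       d = numeric()),
               members = data.frame(restraint = integer(), ai = integer(),
                                    bi = integer(), r0 = numeric()),
               groups = groups, method = method, cutoff = cutoff,
               sourceModel = as.integer(model)))
  }
  eff <- if (method == "r6") {
    s <- rowsum(pe$members$r^-6, pe$members$pair)
    as.vector(s)^(-1 / 6)
  } else {
    as.vector(tapply(pe$members$r, pe$members$pair, min))
  }
  new("RestraintSet",
      restraints = data.frame(ga = pe$pairs$ga, gb = pe$pairs$gb, d = eff),
      members = data.frame(restraint = pe$members$pair, ai = pe$members$ai,
                           bi = pe$members$bi, r0 = pe$members$r),
      groups = groups, method = method, cutoff = cutoff,
      sourceModel = as.integer(model))
}

# selection strings for one group: "A 5 HB1,HB2,HB3"
.group_sel <- function(set, structure, g) {
  a <- atomTable(structure, set@sourceModel)
  idx <- set@groups@hydrogens[[g]]
  list(chain = a$chain[idx[1]], resseq = a$resseq[idx[1]],
       atoms = paste(a$name[idx], collapse = ","))
}

#' Write a restraint set to disk
#'
#' TSV dialect: columns `chain_a`, `resseq_a`, `atoms_a`, `chain_b`,
#' `resseq_b`, `atoms_b`, `d`, `method`. X-PLOR dialect: NOE `assign`
#' statements with bounds `d minus plus` where minus = plus = `width`/2.
#'
#' @param set a [RestraintSet-class].
#' @param structure the structure the set was derived from (for atom names).
#' @param path output path.
#' @param dialect "tsv" (default) or "xplor".
#' @param width flat-bottom width for the X-PLOR bounds (default 0).
#' @return invisibly, `path`.
#' @export
writeRestraints <- function(set, structure, path, dialect = c("tsv", "xplor"),
                            width = 0) {
  dialect <- match.arg(dialect)
  n <- length(set)
  sa <- lapply(seq_len(n), function(i)
    .group_sel(set, structure, set@restraints$ga[i]))
  sb <- lapply(seq_len(n), function(i)
    .group_sel(set, structure, set@restraints$gb[i]))
  if (dialect == "tsv") {
    df <- data.frame(
      chain_a = vapply(sa, `[[`, "", "chain"),
      resseq_a = vapply(sa, function(s) as.integer(s$resseq), 1L),
      atoms_a = vapply(sa, `[[`, "", "atoms"),
      chain_b = vapply(sb, `[[`, "", "chain"),
      resseq_b = vapply(sb, function(s) as.integer(s$resseq), 1L),
      atoms_b = vapply(sb, `[[`, "", "atoms"),
      d = round(set@restraints$d, 4),
      method = rep(set@method, n))
    if (n == 0L)
      df <- data.frame(chain_a = character(), resseq_a = integer(),
                       atoms_a = character(), chain_b = character(),
                       resseq_b = integer(), atoms_b = character(),
                       d = numeric(), method = character())
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    selstr <- function(s) {
      nm <- strsplit(s$atoms, ",")[[1]]
      inner <- paste(paste("name", nm), collapse = " or ")
      sprintf("(segid %s and resid %d and (%s))", s$chain,
              as.integer(s$resseq), inner)
    }
    lines <- vapply(seq_len(n), function(i)
      sprintf("assign %s %s %.3f %.3f %.3f", selstr(sa[[i]]), selstr(sb[[i]]),
              set@restraints$d[i], width / 2, width / 2), "")
    writeLines(c("! NOE-style distance restraints", lines), path)
  }
  invisible(path)
}

#' Read a restraint table
#'
#' Reads the TSV or X-PLOR dialect written by [writeRestraints()]. When
#' `structure` is supplied, atom selections are resolved against it so the
#' returned set can be used for energy evaluation; otherwise only the
#' selection columns and `d` are populated.
#'
#' @param path input path.
#' @param dialect "tsv" (default) or "xplor".
#' @param structure optional [StructureModel-class] to resolve atoms.
#' @param model model index for resolution (default 1).
#' @return a data.frame of restraints (columns as in the TSV dialect, plus
#'   `upper` for X-PLOR input where it equals d + plus).
#' @export
readRestraints <- function(path, dialect = c("tsv", "xplor"),
                           structure = NULL, model = 1L) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer",
                                           "character", "character",
                                           "integer", "character",
                                           "numeric", "character"))
  } else {
    ln <- grep("^assign", readLines(path), value = TRUE)
    pat <- paste0("^assign \\(segid (\\S+) and resid (\\d+) and \\((.*?)\\)\\)",
                  " \\(segid (\\S+) and resid (\\d+) and \\((.*?)\\)\\)",
                  " +([0-9.]+) +([0-9.]+) +([0-9.]+)")
    m <- regmatches(ln, regexec(pat, ln))
    bad <- vapply(m, length, 1L) != 10L
    if (any(bad)) stop("unparseable assign statement at line ",
                       which(bad)[1])
    g <- function(i, f = identity) vapply(m, function(x) f(x[i + 1]),
                                          f("1"))
    names_of <- function(s) paste(gsub("name ", "",
                                       strsplit(s, " or ")[[1]]),
                                  collapse = ",")
    df <- data.frame(
      chain_a = g(1), resseq_a = as.integer(g(2)),
      atoms_a = vapply(g(3), names_of, ""),
      chain_b = g(4), resseq_b = as.integer(g(5)),
      atoms_b = vapply(g(6), names_of, ""),
      d = as.numeric(g(7)), method = "unknown",
      upper = as.numeric(g(7)) + as.numeric(g(9)),
      stringsAsFactors = FALSE)
    rownames(df) <- NULL
  }
  df
}
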