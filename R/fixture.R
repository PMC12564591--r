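# Seeded backtracking solver over binary cells with exact count constraints.
# constraints: list of list(id = chr, cells = int vector, target = int).
# Cells not covered by any constraint are set to 0. Returns
# list(ok = TRUE, assign = 0/1 vector) on success, or
# list(ok = FALSE, fail = ids) naming the constraints involved at the
# deepest point the search reached (the conflicting subset it identified).
solve_count_csp <- function(n_cells, constraints, max_nodes = 2e5) {
  nc <- length(constraints)
  target <- vapply(constraints, function(k) as.integer(k$target), 1L)
  cell_cons <- vector("list", n_cells)
  for (ci in seq_len(nc)) {
    for (cell in constraints[[ci]]$cells) {
      cell_cons[[cell]] <- c(cell_cons[[cell]], ci)
    }
  }
  deg <- lengths(cell_cons)
  involved <- which(deg > 0)
  if (length(involved) == 0) {
    return(list(ok = TRUE, assign = rep(0L, n_cells)))
  }

  # propagation to a fixpoint: saturated constraints force their remaining
  # cells; contradictions surface immediately
  val <- rep(NA_integer_, n_cells)
  val[-involved] <- 0L
  repeat {
    changed <- FALSE
    for (ci in seq_len(nc)) {
      cs <- constraints[[ci]]$cells
      un <- cs[is.na(val[cs])]
      a <- sum(val[cs], na.rm = TRUE)
      if (a > target[ci] || a + length(un) < target[ci]) {
        return(list(ok = FALSE, fail = constraints[[ci]]$id))
      }
      if (length(un) == 0) next
      if (a == target[ci]) {
        val[un] <- 0L
        changed <- TRUE
      } else if (a + length(un) == target[ci]) {
        val[un] <- 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  open <- involved[is.na(val[involved])]
  if (length(open) == 0) return(list(ok = TRUE, assign = val))

  # most-constrained cells first, seeded tie-break
  ord <- open[order(-deg[open], sample.int(length(open)))]
  prefs <- sample(c(0L, 1L), n_cells, replace = TRUE)

  s <- vapply(constraints, function(k) {
    as.integer(sum(val[k$cells], na.rm = TRUE))
  }, 1L)
  r <- vapply(constraints, function(k) {
    as.integer(sum(is.na(val[k$cells])))
  }, 1L)
  nodes <- 0L
  deepest <- 0L
  fail_ids <- character()

  rec <- function(d) {
    if (d > length(ord)) return(TRUE)
    nodes <<- nodes + 1L
    if (nodes > max_nodes) return(FALSE)
    cell <- ord[d]
    touched <- cell_cons[[cell]]
    for (v in c(prefs[cell], 1L - prefs[cell])) {
      ok <- TRUE
      for (ci in touched) {
        s[ci] <<- s[ci] + v
        r[ci] <<- r[ci] - 1L
      }
      for (ci in touched) {
        if (s[ci] > target[ci] || s[ci] + r[ci] < target[ci]) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        val[cell] <<- v
        if (rec(d + 1L)) return(TRUE)
      }
      for (ci in touched) {
        s[ci] <<- s[ci] - v
        r[ci] <<- r[ci] + 1L
      }
    }
    if (d > deepest) {
      deepest <<- d
      fail_ids <<- vapply(constraints[touched], function(k) k$id, "")
    }
    FALSE
  }

  if (rec(1L)) list(ok = TRUE, assign = val) else
    list(ok = FALSE, fail = fail_ids)
}

# enumerate all non-negative integer matrices with given row/column sums
enum_margin_matrices <- function(rsum, csum) {
  nr <- length(rsum)
  nc <- length(csum)
  out <- list()
  fill_row <- function(r, rem_csum, acc) {
    if (r > nr) {
      if (all(rem_csum == 0)) out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    # enumerate compositions of rsum[r] bounded by rem_csum
    comp <- function(j, left, row) {
      if (j > nc) {
        if (left == 0) {
          fill_row(r + 1, rem_csum - row, rbind(acc, row))
        }
        return(invisible())
      }
      for (v in 0:min(left, rem_csum[j])) {
        row[j] <- v
        comp(j + 1, left - v, row)
      }
    }
    comp(1, rsum[r], integer(nc))
  }
  fill_row(1, csum, matrix(0L, 0, nc))
  out
}

ledger_targets <- function(ledger, scope_names_equal = NULL) {
  keep <- vapply(seq_len(nrow(ledger)), function(i) {
    ledger$statistic[i] == "count" && is.na(ledger$indicator[i]) &&
      (is.null(scope_names_equal) ||
         setequal(names(ledger$scope[[i]]), scope_names_equal))
  }, TRUE)
  ledger[keep, ]
}

scopes_equal <- function(a, b) {
  if (!setequal(names(a), names(b))) return(FALSE)
  all(vapply(names(a), function(nm) a[[nm]] == b[[nm]], TRUE))
}

target_by_scope <- function(ledger, statistic, scope) {
  for (i in seq_len(nrow(ledger))) {
    if (ledger$statistic[i] == statistic && is.na(ledger$indicator[i]) &&
        scopes_equal(ledger$scope[[i]], scope)) {
      return(ledger$target[i])
    }
  }
  NULL
}

# demographic skeleton candidates: for each disclosure cell, all joint
# identity-config x race-config contingency matrices consistent with the
# two truth tables' case counts
skeleton_candidates <- function(ledger) {
  id_cond <- c("told3plus", "informed_sex_partners", "lgb", "straight")
  race_cond <- c("told3plus", "informed_sex_partners", "black", "white")
  id_cfg <- ledger_targets(ledger, id_cond)
  race_cfg <- ledger_targets(ledger, race_cond)
  joint <- ledger_targets(ledger, c("told3plus", "informed_sex_partners"))
  if (nrow(id_cfg) == 0 || nrow(race_cfg) == 0 || nrow(joint) == 0) {
    stop("ledger lacks the truth-table case counts needed to build a fixture",
         call. = FALSE)
  }
  cells <- list()
  for (i in seq_len(nrow(joint))) {
    jt <- joint$scope[[i]]
    if (joint$target[i] == 0) next
    pick <- function(cfg) {
      sel <- vapply(cfg$scope, function(s) {
        s$told3plus == jt$told3plus &&
          s$informed_sex_partners == jt$informed_sex_partners
      }, TRUE)
      cfg[sel, ]
    }
    idc <- pick(id_cfg)
    rcc <- pick(race_cfg)
    if (sum(idc$target) != joint$target[i] ||
        sum(rcc$target) != joint$target[i]) {
      stop("truth-table case counts do not sum to the disclosure group sizes",
           call. = FALSE)
    }
    mats <- enum_margin_matrices(idc$target, rcc$target)
    cells[[length(cells) + 1]] <- list(id_cfg = idc, race_cfg = rcc,
                                       mats = mats)
  }
  cells
}

# expand one matrix choice per disclosure cell into a skeleton frame
expand_skeleton <- function(cells, choice) {
  rows <- list()
  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    mat <- cell$mats[[choice[k]]]
    for (r in seq_len(nrow(mat))) {
      for (cc in seq_len(ncol(mat))) {
        cnt <- mat[r, cc]
        if (cnt == 0) next
        idsc <- cell$id_cfg$scope[[r]]
        rcsc <- cell$race_cfg$scope[[cc]]
        rows[[length(rows) + 1]] <- tibble::tibble(
          told3plus = rep(idsc$told3plus, cnt),
          informed_sex_partners = idsc$informed_sex_partners,
          lgb = idsc$lgb, straight = idsc$straight,
          black = rcsc$black, white = rcsc$white,
          race = if (rcsc$black == 1) "black"
                 else if (rcsc$white == 1) "white" else "other",
          sexual_identity = if (idsc$straight == 1) "straight"
                            else "gay_lesbian"
        )
      }
    }
  }
  frame <- dplyr::bind_rows(rows)
  frame$gay_or_lesbian <- as.integer(frame$sexual_identity == "gay_lesbian")
  frame
}

# check every ledger count entry without indicator that is evaluable on
# the (demographic-only) skeleton frame
skeleton_consistent <- function(frame, ledger) {
  for (i in seq_len(nrow(ledger))) {
    if (ledger$statistic[i] != "count" || !is.na(ledger$indicator[i])) next
    rows <- scope_rows(frame, ledger$scope[[i]])
    if (is.null(rows)) next   # needs isolation/quadrant, checked later
    if (sum(rows) != ledger$target[i]) return(FALSE)
  }
  TRUE
}

# distribute a group's burden sum across members: member i gets a score in
# [lb_i, ub_i]; remaining points are spread by seeded draws
distribute_scores <- function(o, iso, S, isolation_min, n_filler, n_items) {
  lb <- ifelse(iso, pmax(o, isolation_min), o)
  ub <- ifelse(iso, pmin(o + n_filler, n_items),
               pmin(o + n_filler, isolation_min - 1))
  if (any(lb > ub)) return(NULL)
  rem <- S - sum(lb)
  if (rem < 0 || rem > sum(ub - lb)) return(NULL)
  sc <- lb
  while (rem > 0) {
    j <- resample(which(sc < ub))
    sc[j] <- sc[j] + 1L
    rem <- rem - 1L
  }
  sc
}

# choose which members of each disclosure side are isolated and assign
# integer scores meeting the per-group sum targets
solve_scores <- function(frame, o, ledger, config, n_filler, n_items) {
  n <- nrow(frame)
  scores <- integer(n)
  k_iso <- list(
    `1` = target_by_scope(ledger, "count", list(quadrant = "high_exposure")),
    `0` = target_by_scope(ledger, "count",
                          list(quadrant = "hidden_vulnerability"))
  )
  for (t in c(1L, 0L)) {
    side <- which(frame$told3plus == t)
    if (length(side) == 0) next
    groups <- split(side, frame$informed_sex_partners[side])
    sums <- lapply(groups, function(m) {
      target_by_scope(ledger, "score_sum",
                      list(told3plus = t,
                           informed_sex_partners =
                             frame$informed_sex_partners[m[1]]))
    })
    kt <- k_iso[[as.character(t)]]
    ng <- lengths(groups)
    allocs <- if (is.null(kt)) {
      list(rep(NA_integer_, length(groups)))   # no isolation constraint
    } else {
      # all ways to split kt isolated members over the side's groups
      grid <- expand.grid(lapply(ng, function(m) 0:m))
      grid <- grid[rowSums(grid) == kt, , drop = FALSE]
      lapply(sample.int(nrow(grid)), function(i) as.integer(grid[i, ]))
    }
    done <- FALSE
    for (al in allocs) {
      sc_side <- vector("list", length(groups))
      ok <- TRUE
      for (g in seq_along(groups)) {
        m <- groups[[g]]
        og <- o[m]
        Sg <- sums[[g]]
        if (is.null(Sg)) Sg <- sum(og)   # unconstrained group: minimal fill
        if (is.na(al[g])) {
          # no isolation-count constraint: treat all as unbounded above
          sc <- distribute_scores(og, rep(TRUE, length(m)), Sg,
                                  0L, n_filler, n_items)
          if (is.null(sc)) { ok <- FALSE; break }
          sc_side[[g]] <- sc
          next
        }
        subs <- utils::combn(length(m), al[g])
        found <- NULL
        for (ci in sample.int(ncol(subs))) {
          iso <- rep(FALSE, length(m))
          iso[subs[, ci]] <- TRUE
          sc <- distribute_scores(og, iso, Sg, config$isolation_min,
                                  n_filler, n_items)
          if (!is.null(sc)) { found <- sc; break }
        }
        if (is.null(found)) { ok <- FALSE; break }
        sc_side[[g]] <- found
      }
      if (ok) {
        for (g in seq_along(groups)) scores[groups[[g]]] <- sc_side[[g]]
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("fixture infeasible: no score assignment satisfies the burden ",
           "sums and isolation counts for told3plus = ", t, call. = FALSE)
    }
  }
  scores
}

#' Reconstruct the 17-record survey fixture from the constraint ledger
#'
#' Solves the constraint-satisfaction problem defined by [compile_ledger()]
#' and returns a participant table on which every published marginal checks
#' true. The solver works in stages: (1) a demographic skeleton is found by
#' enumerating joint identity-by-race assignments consistent with both
#' truth tables' case counts; (2) the five outcome indicators are assigned
#' by a seeded backtracking search over the participant-by-outcome bit
#' matrix with exact count-constraint propagation; (3) isolation scores are
#' chosen to meet the group burden sums and isolated/typology counts, and
#' the ten non-outcome indicators are filled in to realize each score;
#' (4) `people_told` values are drawn compatibly with each respondent's
#' `told3plus` flag (exact counts are not published). The result is
#' deterministic given `seed` and is verified against the full ledger
#' before being returned.
#'
#' @param seed integer seed controlling every random choice.
#' @param ledger a `constraint_ledger`, see [compile_ledger()].
#' @param catalog indicator catalog, see [default_catalog()].
#' @param config threshold configuration, see [threshold_config()].
#' @return A validated 17-row participant tibble.
#' @export
#' @examples
#' fx <- build_fixture(seed = 1)
#' all(check_ledger(fx)$pass)
build_fixture <- function(seed = 1L, ledger = compile_ledger(),
                          catalog = default_catalog(),
                          config = threshold_config()) {
  stopifnot(inherits(ledger, "constraint_ledger"))
  catalog <- validate_catalog(catalog)
  validate_threshold_config(config)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    fixture_solve(ledger, catalog, config)
  })
}

fixture_solve <- function(ledger, catalog, config) {
  cells <- skeleton_candidates(ledger)
  n_items <- nrow(catalog)

  # outcome set = every indicator a ledger constraint mentions
  out_ids <- unique(stats::na.omit(ledger$indicator))
  filler_ids <- setdiff(catalog$id, out_ids)
  K <- length(out_ids)

  n_bi <- target_by_scope(ledger, "count",
                          list(sexual_identity = "bisexual")) %||% 0

  # iterate demographic candidates in seeded order
  n_choices <- vapply(cells, function(c) length(c$mats), 1L)
  combos <- expand.grid(lapply(n_choices, seq_len))
  combo_order <- sample.int(nrow(combos))
  last_fail <- character()

  for (co in combo_order) {
    frame0 <- expand_skeleton(cells,
                              as.integer(unlist(combos[co, , drop = FALSE])))
    n <- nrow(frame0)
    lgb_idx <- which(frame0$lgb == 1)
    if (n_bi > length(lgb_idx)) next
    placements <- if (n_bi == 0) matrix(integer(0), nrow = 0, ncol = 1) else
      utils::combn(lgb_idx, n_bi)
    p_order <- if (ncol(placements) == 0) 1L else
      sample.int(ncol(placements))

    for (pi in p_order) {
      frame <- frame0
      if (n_bi > 0) {
        frame$sexual_identity[placements[, pi]] <- "bisexual"
        frame$gay_or_lesbian <-
          as.integer(frame$sexual_identity == "gay_lesbian")
      }
      if (!skeleton_consistent(frame, ledger)) next

      constraints <- list()
      feasible <- TRUE
      for (i in seq_len(nrow(ledger))) {
        if (ledger$statistic[i] != "count" || is.na(ledger$indicator[i])) next
        rows <- scope_rows(frame, ledger$scope[[i]])
        if (is.null(rows)) { feasible <- FALSE; break }
        members <- which(rows)
        k <- match(ledger$indicator[i], out_ids)
        constraints[[length(constraints) + 1]] <- list(
          id = ledger$id[i],
          cells = (members - 1L) * K + k,
          target = ledger$target[i]
        )
      }
      if (!feasible) next

      # derived constraint: for outcomes with a gay/lesbian subgroup tally,
      # the bisexual members' outcome budget is the LGB truth-table total
      # minus the gay/lesbian target; making it explicit lets propagation
      # reject impossible bisexual placements immediately
      bis <- which(frame$sexual_identity == "bisexual")
      if (length(bis) > 0) {
        id_cond <- c("told3plus", "informed_sex_partners", "lgb", "straight")
        for (i in seq_len(nrow(ledger))) {
          sc <- ledger$scope[[i]]
          if (ledger$statistic[i] != "count" || is.na(ledger$indicator[i]) ||
              !identical(names(sc), "gay_or_lesbian") ||
              sc$gay_or_lesbian != 1) next
          o <- ledger$indicator[i]
          lgb_tot <- 0
          found <- FALSE
          for (j in seq_len(nrow(ledger))) {
            scj <- ledger$scope[[j]]
            if (ledger$statistic[j] == "count" &&
                !is.na(ledger$indicator[j]) && ledger$indicator[j] == o &&
                setequal(names(scj), id_cond) && scj$lgb == 1) {
              lgb_tot <- lgb_tot + ledger$target[j]
              found <- TRUE
            }
          }
          if (!found) next
          constraints[[length(constraints) + 1]] <- list(
            id = paste0("derived_bisexual_", o),
            cells = (bis - 1L) * K + match(o, out_ids),
            target = lgb_tot - ledger$target[i]
          )
        }
      }

      sol <- solve_count_csp(n * K, constraints)
      if (!sol$ok) {
        last_fail <- sol$fail %||% last_fail
        next
      }
      outcome_mat <- matrix(sol$assign, nrow = n, ncol = K, byrow = TRUE)
      colnames(outcome_mat) <- out_ids

      o <- rowSums(outcome_mat)
      scores <- tryCatch(
        solve_scores(frame, o, ledger, config,
                     n_filler = length(filler_ids), n_items = n_items),
        error = function(e) {
          last_fail <<- conditionMessage(e)
          NULL
        })
      if (is.null(scores)) next

      filler_mat <- matrix(0L, nrow = n, ncol = length(filler_ids),
                           dimnames = list(NULL, filler_ids))
      for (m in seq_len(n)) {
        f <- scores[m] - o[m]
        if (f > 0) filler_mat[m, resample(filler_ids, f)] <- 1L
      }

      dmin <- config$disclosure_min
      told <- integer(n)
      for (m in seq_len(n)) {
        told[m] <- if (frame$told3plus[m] == 1) {
          resample(dmin:config$scatter_cap)
        } else {
          resample(0:(dmin - 1))
        }
      }

      ord <- order(frame$told3plus, frame$informed_sex_partners,
                   frame$straight, frame$race, frame$sexual_identity)
      participants <- tibble::tibble(
        pid = sprintf("P%02d", seq_len(n)),
        people_told = told[ord],
        informed_sex_partners = as.integer(frame$informed_sex_partners[ord]),
        sexual_identity = frame$sexual_identity[ord],
        race = frame$race[ord]
      )
      ind <- cbind(outcome_mat, filler_mat)[ord, catalog$id, drop = FALSE]
      for (id in catalog$id) participants[[id]] <- as.integer(ind[, id])

      participants <- as_participants(participants, catalog)
      chk <- check_ledger(participants, ledger, config, catalog)
      if (!all(chk$pass)) {
        stop("internal error: solved fixture violates ledger entries: ",
             paste(chk$id[!chk$pass], collapse = ", "), call. = FALSE)
      }
      return(participants)
    }
  }
  stop("fixture constraints are infeasible; the search failed around ",
       "constraint(s): ",
       if (length(last_fail)) paste(last_fail, collapse = ", ") else
         "(demographic skeleton)", call. = FALSE)
}
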