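# Reference fixed-step simulator.
#
# A resolved network is flattened into instance groups: one per population
# (n = population size), plus, for every projection synapse, one
# weight-update group (n = number of connections) and one postsynapse group
# (n = destination size).  Analog values propagate synchronously (Jacobi):
# every receive port reads the sender's previous-step value, which removes
# any dependence on group evaluation order.  Integration is forward Euler
# with the experiment's dt (ms); time derivatives are in units of the state
# variable per second.  Events and impulses travel through a step-indexed
# delay queue; delays are quantised to round(delay/dt) steps with a minimum
# of one step, so a spike emitted at step k on a d-step connection is acted
# on at step k + d.  Impulse payloads are the value of the sending
# component's symbol named by the impulse send port, sampled at emission.
#
# Per step, in order: (1) analog reads from previous-step send values;
# (2) reduce-port sums; (3) alias evaluation; (4) Euler update;
# (5) condition evaluation (firing on false->true edges, ties resolved in
# declaration order); (6) assignments, regime switches, emissions;
# (7) emissions enqueued with their delays; (8) delivery of due
# events/impulses; (9) logging.

compile_component_runtime <- function(comp) {
  alias_names <- vapply(comp$aliases, `[[`, "", "name")
  deps <- lapply(comp$aliases, function(a)
    intersect(expression_symbols(a$expression), alias_names))
  names(deps) <- alias_names
  order <- alias_topo_order(deps) %||% character()
  aliases <- stats::setNames(lapply(comp$aliases, function(a)
    compile_expression(a$expression)), alias_names)
  regime_names <- vapply(comp$regimes, `[[`, "", "name")
  regimes <- lapply(comp$regimes, function(r) {
    comp_tr <- function(tr) list(
      trigger = tr$trigger,
      trigger_c = if (is.null(tr$trigger)) NULL else
        tryCatch(compile_expression(tr$trigger), error = function(e) NULL),
      assignments = lapply(tr$assignments, compile_expression),
      emits = tr$emits,
      target = match(tr$target_regime, regime_names))
    by_port <- function(trs) {
      out <- list()
      for (tr in trs) {
        k <- tr$trigger
        out[[k]] <- c(out[[k]], list(comp_tr(tr)))
      }
      out
    }
    list(name = r$name,
         derivs = lapply(r$time_derivatives, compile_expression),
         conditions = lapply(r$on_conditions, comp_tr),
         on_events = by_port(r$on_events),
         on_impulses = by_port(r$on_impulses))
  })
  list(aliases = aliases, alias_order = order, regimes = regimes,
       regime_names = regime_names,
       sv_names = vapply(comp$state_variables, `[[`, "", "name"),
       param_names = vapply(comp$parameters, `[[`, "", "name"))
}

group_ports <- function(comp, direction, kinds) {
  Filter(function(p) p$direction == direction && p$kind %in% kinds, comp$ports)
}

# Choose, for each receive port of `down`, the compatible send port of `up`
# (name match preferred, else the unique compatible send); NULL when a port
# stays unwired.
pair_ports <- function(up, down, kind_filter = c("analog", "event", "impulse")) {
  sends <- group_ports(up, "send", kind_filter)
  recvs <- group_ports(down, "receive", kind_filter)
  pairs <- list()
  for (r in recvs) {
    cands <- Filter(function(s) check_port_compatibility(s, r), sends)
    if (length(cands) == 0L) next
    named <- Filter(function(s) s$name == r$name, cands)
    if (length(named) == 1L) cands <- named
    if (length(cands) > 1L)
      spml_error("spml_wiring_error",
                 sprintf("ambiguous wiring \"%s\" -> \"%s\" for port \"%s\"",
                         up$name, down$name, r$name))
    pairs[[length(pairs) + 1L]] <- list(send = cands[[1L]], recv = r)
  }
  pairs
}

delay_to_steps <- function(delay_ms, dt) pmax(1L, as.integer(round(delay_ms / dt)))

new_group <- function(id, comp, n, seed_fn, properties) {
  rt <- compile_component_runtime(comp)
  P <- list(); S <- list()
  for (nm in rt$param_names) {
    v <- properties[[nm]]
    P[[nm]] <- if (is.null(v)) rep(0, n) else sample_property(v, n, seed_fn(nm))
  }
  for (nm in rt$sv_names) {
    v <- properties[[nm]]
    S[[nm]] <- if (is.null(v)) rep(0, n) else sample_property(v, n, seed_fn(nm))
  }
  init <- match(comp$initial_regime, rt$regime_names)
  env <- new.env(parent = spml_fun_env())
  for (nm in names(P)) assign(nm, P[[nm]], envir = env)
  list(id = id, comp = comp, rt = rt, n = n, P = P, S = S,
       regime = rep(init, n), env = env,
       analog_in = list(),      # recv port -> list of source specs
       prev_send = list(),      # send symbol -> previous-step values
       cond_prev = NULL)
}

# --- runtime construction ---------------------------------------------------

#' Build a runtime model
#'
#' Resolves an experiment against a project's network: applies property
#' overrides, samples every property (seeded from the master seed by stable
#' hashing of the property path), instantiates or regenerates connectivity,
#' quantises delays to steps, and wires all ports with compatibility
#' enforced.  The result is deterministic: identical (project, experiment,
#' master_seed) gives an identical runtime.
#'
#' @param proj An `spml_project`.
#' @param exp An `spml_experiment` (or the name of one in the project).
#' @param master_seed Integer master seed; all randomness derives from it.
#' @return An `spml_runtime` ready for [run_simulation()].
#' @export
build_runtime <- function(proj, exp, master_seed = 1L) {
  if (is.character(exp)) {
    hit <- Find(function(e) e$name == exp, proj$experiments)
    if (is.null(hit))
      spml_error("spml_contract_error",
                 sprintf("experiment \"%s\" not found in project", exp))
    exp <- hit
  }
  comps <- proj$components
  viol <- validate_network(proj$network, comps)
  if (length(viol) > 0L)
    spml_error("spml_validation_error",
               sprintf("network is invalid: %s",
                       paste(vapply(viol, `[[`, "", "message"), collapse = "; ")))
  viol <- validate_experiment(exp, proj$network, comps)
  if (length(viol) > 0L)
    spml_error("spml_validation_error",
               sprintf("experiment is invalid: %s",
                       paste(vapply(viol, `[[`, "", "message"), collapse = "; ")))
  net <- apply_property_changes(proj$network, exp)
  dt <- exp$dt

  groups <- list()
  routes <- list()   # routes[[gid]][[send port]] = list(route entries)
  add_route <- function(gid, port, entry) {
    r <- routes[[gid]] %||% list()
    r[[port]] <- c(r[[port]], list(entry))
    routes[[gid]] <<- r
  }
  add_analog_source <- function(gid, recv_port, src) {
    g <- groups[[gid]]
    g$analog_in[[recv_port]] <- c(g$analog_in[[recv_port]], list(src))
    groups[[gid]] <<- g
  }

  pop_sizes <- stats::setNames(
    vapply(net$populations, `[[`, 0L, "size"),
    vapply(net$populations, `[[`, "", "name"))

  for (p in net$populations) {
    seed_fn <- function(nm) derive_seed(master_seed,
                                        paste0("prop/", p$name, "/", nm))
    groups[[p$name]] <- new_group(p$name, comps[[p$component_ref]], p$size,
                                  seed_fn, p$properties)
  }

  wire_stage <- function(up_gid, down_gid, map, conn = NULL) {
    # map: "index" (map_idx), "reduce" (conn_dst), or "identity"
    up <- groups[[up_gid]]; down <- groups[[down_gid]]
    pairs <- pair_ports(up$comp, down$comp, "analog")
    for (pr in pairs) {
      src <- switch(map$type,
        index = list(type = "index", group = up_gid, sym = pr$send$name,
                     map = map$map),
        reduce = list(type = "reduce", group = up_gid, sym = pr$send$name,
                      dst = map$dst),
        identity = list(type = "index", group = up_gid, sym = pr$send$name,
                        map = seq_len(down$n)))
      if (pr$recv$reduce_rule != "sum" &&
          length(groups[[down_gid]]$analog_in[[pr$recv$name]] %||% list()) > 0L)
        spml_error("spml_wiring_error",
                   sprintf("port \"%s\" of \"%s\" wired twice without reduce_rule=sum",
                           pr$recv$name, down_gid))
      add_analog_source(down_gid, pr$recv$name, src)
    }
    # event/impulse routes
    for (pr in pair_ports(up$comp, down$comp, c("event", "impulse"))) {
      entry <- list(target = down_gid, port = pr$recv$name,
                    kind = pr$send$kind,
                    payload_sym = if (pr$send$kind == "impulse") pr$send$name
                    else NULL)
      if (map$type == "index") {
        tb <- vector("list", up$n)
        db <- vector("list", up$n)
        for (i in seq_len(up$n)) {
          tb[[i]] <- which(map$map_ev_src == i)   # connections fed by src i
          db[[i]] <- map$delay_steps[tb[[i]]]
        }
        entry$targets_by_src <- tb; entry$delays_by_src <- db
      } else if (map$type == "reduce") {
        entry$targets_by_src <- lapply(map$dst, function(d) d)
        entry$delays_by_src <- lapply(seq_along(map$dst), function(i) 1L)
      } else { # identity
        entry$targets_by_src <- as.list(seq_len(up$n))
        entry$delays_by_src <- lapply(seq_len(up$n), function(i) 1L)
      }
      add_route(up_gid, pr$send$name, entry)
    }
  }

  resolve_connectivity <- function(sy, pr, si, src_size, dst_size) {
    conn <- sy$connectivity
    if (inherits(conn, "spml_connection_list") && !is.null(conn$recipe)) {
      rc <- conn$recipe
      if (needs_regeneration(rc, rc$source_text, rc$values, src_size, dst_size)) {
        src_pop <- find_population(net, pr$source)
        dst_pop <- find_population(net, pr$destination)
        get_coords <- function(pop) {
          if (is.null(pop$layout_ref) ||
              is.null(proj$layouts[[pop$layout_ref]]))
            spml_error("spml_regeneration_error",
                       sprintf("connection list for %s->%s needs regeneration but population \"%s\" has no layout",
                               pr$source, pr$destination, pop$name))
          generate_layout(proj$layouts[[pop$layout_ref]], pop$size)
        }
        return(regenerate_from_recipe(
          generation_recipe(rc$source_text, rc$values, src_size, dst_size,
                            rc$weight_target),
          get_coords(src_pop), get_coords(dst_pop)))
      }
      return(conn)
    }
    instantiate_connectivity(conn, src_size, dst_size,
                             seed = derive_seed(master_seed,
                                                paste0("conn/", pr$source, "/",
                                                       pr$destination, "/", si)),
                             recurrent = pr$source == pr$destination)
  }

  for (pr in net$projections) {
    src_size <- pop_sizes[[pr$source]]; dst_size <- pop_sizes[[pr$destination]]
    for (si in seq_along(pr$synapses)) {
      sy <- pr$synapses[[si]]
      cl <- resolve_connectivity(sy, pr, si, src_size, dst_size)
      n_conn <- length(cl$src)
      if (n_conn == 0L) next
      base <- sprintf("%s->%s/%d", pr$source, pr$destination, si)
      wu_gid <- paste0(base, "/wu"); ps_gid <- paste0(base, "/ps")
      wu_props <- sy$weight_update$properties
      if (!is.null(cl$weights)) {
        wt <- (cl$recipe$weight_target %||% "w")
        wu_props[[wt]] <- NULL  # replaced by explicit per-connection weights
      }
      seed_wu <- function(nm) derive_seed(master_seed,
                                          paste0("prop/", wu_gid, "/", nm))
      groups[[wu_gid]] <- new_group(wu_gid, comps[[sy$weight_update$component_ref]],
                                    n_conn, seed_wu, wu_props)
      if (!is.null(cl$weights)) {
        wt <- (cl$recipe$weight_target %||% "w")
        g <- groups[[wu_gid]]
        if (wt %in% names(g$P)) {
          g$P[[wt]] <- cl$weights
          assign(wt, cl$weights, envir = g$env)
        } else if (wt %in% names(g$S)) g$S[[wt]] <- cl$weights
        else spml_error("spml_wiring_error",
                        sprintf("weight target \"%s\" not found on \"%s\"",
                                wt, sy$weight_update$component_ref))
        groups[[wu_gid]] <- g
      }
      seed_ps <- function(nm) derive_seed(master_seed,
                                          paste0("prop/", ps_gid, "/", nm))
      groups[[ps_gid]] <- new_group(ps_gid, comps[[sy$postsynapse$component_ref]],
                                    dst_size, seed_ps, sy$postsynapse$properties)
      steps <- delay_to_steps(cl$delay, dt)
      # source population -> weight update (per connection)
      wire_stage(pr$source, wu_gid,
                 list(type = "index", map = cl$src + 1L,
                      map_ev_src = cl$src + 1L, delay_steps = steps))
      # weight update -> postsynapse (reduce over connections per destination)
      wire_stage(wu_gid, ps_gid, list(type = "reduce", dst = cl$dst + 1L))
      # postsynapse -> destination neuron (identity)
      wire_stage(ps_gid, pr$destination, list(type = "identity"))
    }
  }

  for (gi in net$generic_inputs) {
    cl <- instantiate_connectivity(gi$connectivity,
                                   pop_sizes[[gi$src_population]],
                                   pop_sizes[[gi$dst_population]],
                                   seed = derive_seed(master_seed,
                                                      paste0("gi/", gi$src_population,
                                                             "/", gi$dst_population)))
    up <- groups[[gi$src_population]]; down <- groups[[gi$dst_population]]
    sp <- find_port(up$comp, gi$src_port); dp <- find_port(down$comp, gi$dst_port)
    if (sp$kind == "analog") {
      add_analog_source(gi$dst_population, dp$name,
                        list(type = "pairs", group = gi$src_population,
                             sym = sp$name, src = cl$src + 1L, dst = cl$dst + 1L))
    } else {
      steps <- delay_to_steps(cl$delay, dt)
      tb <- vector("list", up$n); db <- vector("list", up$n)
      for (i in seq_len(up$n)) {
        sel <- which(cl$src + 1L == i)
        tb[[i]] <- cl$dst[sel] + 1L
        db[[i]] <- steps[sel]
      }
      entry <- list(target = gi$dst_population, port = dp$name,
                    kind = sp$kind,
                    payload_sym = if (sp$kind == "impulse") sp$name else NULL,
                    targets_by_src = tb, delays_by_src = db)
      add_route(gi$src_population, sp$name, entry)
    }
  }

  # external (experiment) inputs
  ext_analog <- list(); ext_spikes <- list()
  for (inp in exp$inputs) {
    if (inp$variant %in% c("constant", "time_varying")) {
      ext_analog[[length(ext_analog) + 1L]] <- inp
      add_analog_source(inp$target, inp$port,
                        list(type = "external", spec = inp))
    } else {
      steps <- unique(as.integer(round(spike_times(inp) * 1000 / dt)))
      ext_spikes[[length(ext_spikes) + 1L]] <-
        list(target = inp$target, port = inp$port, steps = steps,
             indices = if (is.null(inp$indices))
               seq_len(groups[[inp$target]]$n) else inp$indices + 1L)
    }
  }

  n_steps <- floor(exp$duration * 1000 / dt)
  structure(list(groups = groups, routes = routes, ext_spikes = ext_spikes,
                 dt = dt, n_steps = as.integer(n_steps), exp = exp,
                 master_seed = as.integer(master_seed)),
            class = "spml_runtime")
}

#' @export
print.spml_runtime <- function(x, ...) {
  cat(sprintf("<runtime: %d group(s), dt = %g ms, %d step(s)>\n",
              length(x$groups), x$dt, x$n_steps))
  invisible(x)
}

# --- stepping ---------------------------------------------------------------

refresh_env <- function(g) {
  env <- g$env
  for (nm in names(g$S)) assign(nm, g$S[[nm]], envir = env)
  for (nm in g$rt$alias_order)
    assign(nm, eval_compiled(g$rt$aliases[[nm]], env), envir = env)
  env
}

snapshot_sends <- function(g) {
  env <- g$env
  out <- list()
  for (p in group_ports(g$comp, "send", c("analog", "impulse")))
    out[[p$name]] <- eval(as.name(p$name), env)
  out
}

# sends: named list group id -> list(send symbol -> previous-step values)
compute_analog_inputs <- function(g, sends, t_s) {
  env <- g$env
  for (port_name in names(g$analog_in)) {
    total <- numeric(g$n)
    for (src in g$analog_in[[port_name]]) {
      val <- switch(src$type,
        index = {
          sv <- sends[[src$group]][[src$sym]]
          if (is.null(sv)) numeric(g$n) else sv[src$map]
        },
        reduce = {
          sv <- sends[[src$group]][[src$sym]]
          if (is.null(sv)) numeric(g$n) else {
            acc <- numeric(g$n)
            agg <- rowsum(sv, src$dst)
            acc[as.integer(rownames(agg))] <- agg[, 1L]
            acc
          }
        },
        pairs = {
          sv <- sends[[src$group]][[src$sym]]
          if (is.null(sv)) numeric(g$n) else {
            acc <- numeric(g$n)
            agg <- rowsum(sv[src$src], src$dst)
            acc[as.integer(rownames(agg))] <- agg[, 1L]
            acc
          }
        },
        external = {
          spec <- src$spec
          v <- input_value(spec, t_s)
          acc <- numeric(g$n)
          idx <- if (is.null(spec$indices)) seq_len(g$n) else spec$indices + 1L
          acc[idx] <- v
          acc
        })
      total <- total + val
    }
    assign(port_name, total, envir = env)
  }
  # unwired receive ports read 0
  for (p in group_ports(g$comp, "receive", "analog"))
    if (is.null(g$analog_in[[p$name]])) assign(p$name, numeric(g$n), envir = env)
  env
}

#' Run a built runtime
#'
#' Integrates the model for the experiment's duration and returns the log
#' set.  Raises a simulation error naming the population, neuron, variable
#' and step if any state becomes non-finite.
#'
#' @param rt An `spml_runtime` from [build_runtime()].
#' @param progress Unused hook for callers.
#' @return An `spml_logset`: `$analog` (per logger: time vector in s and a
#'   time x index matrix), `$events` (per logger: data.frame time, index)
#'   and `$meta` (dt, steps, seed).
#' @export
run_simulation <- function(rt, progress = FALSE) {
  dt <- rt$dt; dt_s <- dt / 1000
  groups <- rt$groups
  n_steps <- rt$n_steps

  queue <- vector("list", n_steps + 2L)  # deliveries indexed by step + 1
  enqueue <- function(due_step, item) {
    if (due_step <= n_steps) {
      slot <- due_step + 1L
      queue[[slot]] <<- c(queue[[slot]], list(item))
    }
  }
  for (es in rt$ext_spikes) for (s in es$steps)
    enqueue(s, list(target = es$target, port = es$port, kind = "event",
                    inst = es$indices, payload = NULL))

  emit <- function(gid, port, idx, step) {
    rl <- rt$routes[[gid]][[port]]
    if (is.null(rl)) return(invisible())
    for (entry in rl) {
      payload <- if (!is.null(entry$payload_sym))
        groups[[gid]]$env_payload[[entry$payload_sym]] else NULL
      for (i in idx) {
        tgt <- entry$targets_by_src[[i]]
        if (length(tgt) == 0L) next
        dl <- entry$delays_by_src[[i]]
        for (k in seq_along(tgt))
          enqueue(step + dl[[k]],
                  list(target = entry$target, port = entry$port,
                       kind = entry$kind, inst = tgt[[k]],
                       payload = if (is.null(payload)) NULL else payload[[i]]))
      }
    }
    invisible()
  }

  # event log accumulators
  loggers <- rt$exp$loggers
  analog_logs <- list(); event_logs <- list()
  for (lg in loggers) {
    g <- groups[[lg$target]]
    idx <- if (is.null(lg$indices)) seq_len(g$n) else lg$indices + 1L
    if (lg$kind == "analog") {
      analog_logs[[lg$name]] <- list(logger = lg, idx = idx,
                                     data = matrix(NA_real_, n_steps + 1L,
                                                   length(idx)))
    } else {
      event_logs[[lg$name]] <- list(logger = lg, idx = idx,
                                    time = numeric(), index = integer())
    }
  }
  spikes_this_step <- list()  # gid -> list(port -> idx) for event logging

  apply_transition_set <- function(g, trs, fired, payload_port = NULL,
                                   payload = NULL, step) {
    # fired: integer instance indices (1-based); trs: one compiled transition
    env <- g$env
    if (!is.null(payload_port)) assign(payload_port, payload, envir = env)
    for (nm in names(trs$assignments)) {
      val <- eval_compiled(trs$assignments[[nm]], env)
      if (length(val) == 1L) {
        g$S[[nm]][fired] <- val
      } else g$S[[nm]][fired] <- val[fired]
      assign(nm, g$S[[nm]], envir = env)
    }
    g$regime[fired] <- trs$target
    for (em in trs$emits) {
      p <- find_port(g$comp, em)
      if (p$kind == "impulse") {
        g$env_payload[[em]] <- eval(as.name(em), env)
      }
      spikes_this_step[[g$id]][[em]] <<-
        c(spikes_this_step[[g$id]][[em]] %||% integer(), fired)
      groups[[g$id]] <<- g   # emit() reads env_payload through groups
      emit(g$id, em, fired, step)
      g <- groups[[g$id]]
    }
    g
  }

  # initial env fill (inputs at t = 0, aliases on initial state)
  for (gid in names(groups)) {
    g <- groups[[gid]]
    g$env_payload <- list()
    groups[[gid]] <- g
  }
  # initial snapshot: external inputs at t = 0, internal sends read as 0
  sends <- list()
  for (gid in names(groups)) {
    g <- groups[[gid]]
    compute_analog_inputs(g, list(), 0)
    refresh_env(g)
    sends[[gid]] <- snapshot_sends(g)
    # initial condition values (edge detection baseline)
    g$cond_prev <- lapply(seq_along(g$rt$regimes), function(ri) {
      lapply(g$rt$regimes[[ri]]$conditions, function(cd)
        as.logical(eval_compiled(cd$trigger_c, g$env)) & rep(TRUE, g$n))
    })
    groups[[gid]] <- g
  }

  log_row <- function(row) {
    for (nm in names(analog_logs)) {
      al <- analog_logs[[nm]]
      g <- groups[[al$logger$target]]
      vals <- eval(as.name(al$logger$port), g$env)
      analog_logs[[nm]]$data[row, ] <<- vals[al$idx]
    }
  }
  log_row(1L)

  for (step in seq_len(n_steps)) {
    t_s <- step * dt_s
    spikes_this_step <- list()

    # phases 1-3: inputs, reductions, aliases (from previous-step sends)
    for (gid in names(groups)) {
      g <- groups[[gid]]
      compute_analog_inputs(g, sends, t_s)
      refresh_env(g)
      groups[[gid]] <- g
    }

    # phase 4: Euler update
    for (gid in names(groups)) {
      g <- groups[[gid]]
      if (length(g$S) == 0L) next
      env <- g$env
      n_regimes <- length(g$rt$regimes)
      if (n_regimes == 1L) {
        for (nm in names(g$rt$regimes[[1L]]$derivs)) {
          d <- eval_compiled(g$rt$regimes[[1L]]$derivs[[nm]], env)
          g$S[[nm]] <- g$S[[nm]] + dt_s * d
        }
      } else {
        newS <- g$S
        for (ri in seq_len(n_regimes)) {
          mask <- g$regime == ri
          if (!any(mask)) next
          for (nm in names(g$rt$regimes[[ri]]$derivs)) {
            d <- eval_compiled(g$rt$regimes[[ri]]$derivs[[nm]], env)
            if (length(d) == 1L) d <- rep(d, g$n)
            newS[[nm]][mask] <- g$S[[nm]][mask] + dt_s * d[mask]
          }
        }
        g$S <- newS
      }
      for (nm in names(g$S)) {
        bad <- !is.finite(g$S[[nm]])
        if (any(bad))
          spml_error("spml_simulation_error",
                     sprintf("non-finite state: population \"%s\", neuron %d, variable \"%s\", step %d",
                             gid, which(bad)[[1L]] - 1L, nm, step))
        assign(nm, g$S[[nm]], envir = g$env)
      }
      # refresh aliases on the updated state for triggers and sends
      refresh_env(g)
      groups[[gid]] <- g
    }

    # phases 5-7: conditions, assignments, emissions
    for (gid in names(groups)) {
      g <- groups[[gid]]
      for (ri in seq_along(g$rt$regimes)) {
        conds <- g$rt$regimes[[ri]]$conditions
        for (ci in seq_along(conds)) {
          cd <- conds[[ci]]
          cur <- as.logical(eval_compiled(cd$trigger_c, g$env))
          if (length(cur) == 1L) cur <- rep(cur, g$n)
          prev <- g$cond_prev[[ri]][[ci]]
          fired <- which(cur & !prev & (g$regime == ri))
          g$cond_prev[[ri]][[ci]] <- cur
          if (length(fired) > 0L) {
            groups[[gid]] <- g
            g <- apply_transition_set(g, cd, fired, step = step)
            refresh_env(g)
          }
        }
      }
      groups[[gid]] <- g
    }

    # phase 8: deliver due events/impulses
    bucket <- queue[[step + 1L]]
    queue[[step + 1L]] <- list()
    for (item in bucket) {
      g <- groups[[item$target]]
      inst <- item$inst
      handler_field <- if (item$kind == "event") "on_events" else "on_impulses"
      for (i in inst) {
        trs_list <- g$rt$regimes[[g$regime[[i]]]][[handler_field]][[item$port]]
        if (is.null(trs_list)) next
        for (trs in trs_list) {
          groups[[item$target]] <- g
          g <- apply_transition_set(g, trs, i,
                                    payload_port = if (item$kind == "impulse")
                                      item$port else NULL,
                                    payload = item$payload, step = step)
        }
      }
      refresh_env(g)
      groups[[item$target]] <- g
    }

    # event logging
    for (nm in names(event_logs)) {
      el <- event_logs[[nm]]
      fired <- spikes_this_step[[el$logger$target]][[el$logger$port]]
      if (!is.null(fired)) {
        keep <- fired[fired %in% el$idx]
        if (length(keep) > 0L) {
          event_logs[[nm]]$time <- c(el$time, rep(t_s, length(keep)))
          event_logs[[nm]]$index <- c(el$index, keep - 1L)
        }
      }
    }

    # phase 9: snapshot sends for the next step, analog logging
    for (gid in names(groups))
      sends[[gid]] <- snapshot_sends(groups[[gid]])
    log_row(step + 1L)
  }

  times <- seq(0, by = dt_s, length.out = n_steps + 1L)
  analog <- lapply(analog_logs, function(al)
    list(logger = al$logger, time = times, data = al$data,
         indices = al$idx - 1L))
  events <- lapply(event_logs, function(el)
    list(logger = el$logger,
         spikes = data.frame(time = el$time, index = el$index)))
  structure(list(analog = analog, events = events,
                 meta = list(dt = dt, n_steps = n_steps,
                             duration = rt$exp$duration,
                             seed = rt$master_seed)),
            class = "spml_logset")
}

#' @export
print.spml_logset <- function(x, ...) {
  cat(sprintf("<log set: %d analog log(s), %d event log(s), %d step(s) at dt = %g ms>\n",
              length(x$analog), length(x$events), x$meta$n_steps, x$meta$dt))
  invisible(x)
}

#' Build and run in one call
#' @inheritParams build_runtime
#' @export
run_experiment <- function(proj, exp, master_seed = 1L) {
  run_simulation(build_runtime(proj, exp, master_seed))
}

#' Write a log set to a directory
#'
#' Analog logs are written as raw little-endian 64-bit floats in row-major
#' (time x indices) order plus a portability CSV; event logs as CSV
#' (`time,index`).  Every log gets the XML descriptor of
#' [write_log_metadata()] alongside.
#'
#' @param logs An `spml_logset`.
#' @param dir Output directory.
#' @return Character vector of files written.
#' @export
write_logset <- function(logs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in names(logs$analog)) {
    al <- logs$analog[[nm]]
    bin <- file.path(dir, paste0(nm, ".bin"))
    con <- file(bin, "wb")
    writeBin(as.vector(t(al$data)), con, size = 8L, endian = "little")
    close(con)
    csv <- file.path(dir, paste0(nm, ".csv"))
    df <- data.frame(time = al$time)
    for (j in seq_along(al$indices))
      df[[paste0("channel", al$indices[[j]])]] <- al$data[, j]
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
    meta <- file.path(dir, paste0(nm, ".xml"))
    write_log_metadata(al$logger, nrow(al$data), logs$meta$dt,
                       data_file = basename(bin), path = meta)
    written <- c(written, bin, csv, meta)
  }
  for (nm in names(logs$events)) {
    el <- logs$events[[nm]]
    csv <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(el$spikes, csv, row.names = FALSE, quote = FALSE)
    meta <- file.path(dir, paste0(nm, ".xml"))
    write_log_metadata(el$logger, nrow(el$spikes), logs$meta$dt,
                       data_file = basename(csv), path = meta)
    written <- c(written, csv, meta)
  }
  written
}
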