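"""Coalescent simulation backend.

Reads a JSON config describing a demographic model (populations, splits,
admixture pulses, migration, optional census for local-ancestry tracts)
or a single-population selective sweep, simulates haplotypes with
msprime, and writes a phased VCF plus an optional ancestry-tract TSV.

Invoked by the R package as:  python msprime_sim.py <config.json>
Not intended to be run by hand; the R wrappers build the config.
"""

import json
import math
import sys

import msprime
import numpy as np
import tskit


def build_demography(spec):
    dem = msprime.Demography()
    for p in spec["populations"]:
        kw = {}
        # contemporary populations that are also split ancestors (e.g. the
        # African population once an East-African branch exists) must be
        # explicitly active from the present
        if p.get("active") is not None:
            kw["initially_active"] = bool(p["active"])
        dem.add_population(
            name=p["name"],
            initial_size=p["size"],
            growth_rate=p.get("growth", 0.0),
            **kw,
        )
    for m in spec.get("migrations", []):
        dem.set_symmetric_migration_rate([m["a"], m["b"]], m["rate"])
    for ev in spec.get("events", []):
        t = ev["time"]
        if ev["type"] == "pulse":
            # forward-time: `dest` receives `fraction` from `source`;
            # msprime mass migration is backwards in time.
            dem.add_mass_migration(
                time=t, source=ev["dest"], dest=ev["source"],
                proportion=ev["fraction"],
            )
        elif ev["type"] == "split":
            dem.add_population_split(
                time=t, derived=ev["derived"], ancestral=ev["ancestral"]
            )
        elif ev["type"] == "size_change":
            dem.add_population_parameters_change(
                time=t, population=ev["population"],
                initial_size=ev.get("size"),
                growth_rate=ev.get("growth", 0.0),
            )
        elif ev["type"] == "migration_change":
            dem.add_symmetric_migration_rate_change(
                time=t, populations=[ev["a"], ev["b"]], rate=ev["rate"]
            )
        else:
            raise ValueError("unknown event type: %s" % ev["type"])
    census = spec.get("census_time")
    if census is not None:
        dem.add_census(time=float(census))
    dem.sort_events()
    return dem


def logistic_frequency(s, tau, n_eff):
    """Deterministic additive-selection trajectory from 1/(2N) after tau
    generations: solution of dx/dt = s x (1 - x)."""
    x0 = 1.0 / (2.0 * n_eff)
    if s <= 0 or tau <= 0:
        return x0
    odds0 = x0 / (1.0 - x0)
    odds = odds0 * math.exp(s * tau)
    return odds / (1.0 + odds)


def fixation_time(s, n_eff):
    """Generations for the deterministic trajectory to go from 1/(2N) to
    1 - 1/(2N)."""
    return 2.0 * math.log(2.0 * n_eff - 1.0) / s


def sweep_models(cfg, n_eff):
    s = float(cfg["s"])
    tau = float(cfg["tau"])
    cap = 1.0 - 1.0 / (2.0 * n_eff)
    x0 = 1.0 / (2.0 * n_eff)
    condition = cfg.get("condition", "frequency")
    if condition == "fixation":
        end_freq = cap
        t_since_fix = max(0.0, tau - fixation_time(s, n_eff))
    elif condition == "frequency":
        end_freq = min(logistic_frequency(s, tau, n_eff), cap)
        t_since_fix = 0.0
    else:
        raise ValueError("unknown sweep condition: %s" % condition)
    if end_freq <= x0:
        raise ValueError(
            "sweep (s=%g, tau=%g) never escapes the initial frequency" % (s, tau)
        )
    # msprime's SweepGenicSelection parameter is the homozygote advantage;
    # our s is the per-copy (additive) advantage.
    sweep = msprime.SweepGenicSelection(
        position=float(cfg["position"]),
        start_frequency=x0,
        end_frequency=end_freq,
        s=2.0 * s,
        dt=1.0 / (40.0 * n_eff),
    )
    models = []
    if t_since_fix > 0:
        models.append(msprime.StandardCoalescent(duration=t_since_fix))
    models.append(sweep)
    models.append(msprime.StandardCoalescent())
    meta = {
        "condition": condition,
        "end_frequency": end_freq,
        "generations_since_fixation": t_since_fix,
    }
    return models, meta


def write_tracts(ts, census_time, labels, hap_names, chrom, path):
    node_pop = ts.tables.nodes.population
    node_time = ts.tables.nodes.time
    pop_names = {p.id: (p.metadata or {}).get("name", str(p.id))
                 for p in ts.populations()}
    census_nodes = np.where(node_time == census_time)[0].astype(np.int32)
    samples = ts.samples()
    anc = ts.tables.link_ancestors(samples, census_nodes)
    rows = []
    for left, right, parent, child in zip(anc.left, anc.right, anc.parent,
                                          anc.child):
        pop = pop_names[node_pop[parent]]
        rows.append((int(child), float(left), float(right),
                     labels.get(pop, pop)))
    rows.sort()
    with open(path, "w") as fh:
        fh.write("chrom\tstart\tend\thaplotype\tancestry\n")
        for child, left, right, lab in rows:
            fh.write("%s\t%d\t%d\t%s\t%s\n" %
                     (chrom, int(left), int(right), hap_names[child], lab))


def main(cfg_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    seed = int(cfg["seed"])
    rng = np.random.RandomState(seed)
    anc_seed, mut_seed = [int(x) for x in rng.randint(1, 2**31 - 1, 2)]
    dem = build_demography(cfg["demography"])
    samples = {k: int(v) for k, v in cfg["samples"].items()}

    meta = {"engine": "msprime", "version": msprime.__version__, "seed": seed}
    if cfg.get("sweep"):
        pops = cfg["demography"]["populations"]
        if len(pops) != 1:
            raise ValueError("sweep simulation requires a single population")
        n_eff = float(pops[0]["size"])
        models, sweep_meta = sweep_models(cfg["sweep"], n_eff)
        meta.update(sweep_meta)
        retries = 0
        max_retries = int(cfg["sweep"].get("max_retries", 50))
        while True:
            try:
                ts = msprime.sim_ancestry(
                    samples=samples, demography=dem,
                    sequence_length=cfg["L"],
                    recombination_rate=cfg["r"],
                    model=models, random_seed=anc_seed + retries,
                )
                break
            except Exception:
                retries += 1
                if retries >= max_retries:
                    raise RuntimeError(
                        "sweep trajectory failed after %d retries" % retries
                    )
        meta["retries"] = retries
    else:
        ts = msprime.sim_ancestry(
            samples=samples, demography=dem, sequence_length=cfg["L"],
            recombination_rate=cfg["r"], random_seed=anc_seed,
        )
    ts = msprime.sim_mutations(ts, rate=cfg["mu"], random_seed=mut_seed)

    # individual/haplotype names in sampling order, grouped by population
    ind_names = []
    pop_of_ind = {}
    for ind in ts.individuals():
        pop = ts.node(ind.nodes[0]).population
        pop_of_ind[ind.id] = pop
    counters = {}
    pop_names = {p.id: (p.metadata or {}).get("name", str(p.id))
                 for p in ts.populations()}
    for ind in ts.individuals():
        pname = pop_names[pop_of_ind[ind.id]]
        counters[pname] = counters.get(pname, 0) + 1
        ind_names.append("%s_%03d" % (pname, counters[pname]))
    hap_names = {}
    for ind, name in zip(ts.individuals(), ind_names):
        for k, node in enumerate(ind.nodes):
            hap_names[int(node)] = "%s_h%d" % (name, k + 1)

    chrom = str(cfg.get("chrom", "1"))
    with open(cfg["out_vcf"], "w") as fh:
        ts.write_vcf(fh, individual_names=ind_names, contig_id=chrom,
                     allow_position_zero=True)

    if cfg.get("out_tracts"):
        census = cfg["demography"].get("census_time")
        if census is None:
            raise ValueError("tracts requested but no census_time in model")
        write_tracts(ts, float(census),
                     cfg["demography"].get("ancestry_labels", {}),
                     hap_names, chrom, cfg["out_tracts"])

    if cfg.get("out_meta"):
        meta["num_sites"] = ts.num_sites
        meta["hap_names"] = [hap_names[int(n)] for n in ts.samples()]
        meta["populations"] = [pop_names[ts.node(n).population]
                               for n in ts.samples()]
        with open(cfg["out_meta"], "w") as fh:
            json.dump(meta, fh, indent=1)


if __name__ == "__main__":
    main(sys.argv[1])
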