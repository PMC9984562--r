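"""Coalescent engine for the admixsim module.

Simulates a two-source admixture (source-1 "Jomon"-like lineage receiving
one-way migration from a source-2 "continental"-like lineage) with msprime,
and writes, per replicate:

  rep_<seed>/sites.tsv   pos (1-based), origin_pop, origin_time, haplotypes
                         (one 0/1 character per haplotype, derived allele = 1)
  rep_<seed>/tracts.tsv  hap, start, end, source  (0-based half-open bp,
                         source in {1, 2}; haplotypes of the modern admixed
                         group only, numbered 0..n-1)
  rep_<seed>/meta.json   echo of the model, seed, and group layout

Haplotype column order: modern admixed, modern source-2, source-1 sampled at
adm_start_gen, source-2 sampled at adm_start_gen (n_hap_per_group each).

Ancestry truth uses a census just older than adm_start_gen plus
tables.link_ancestors; mutation origin population is the population of the
carrying lineage at the mutation's time, reconstructed from migration
records. Only biallelic single-mutation sites are emitted.

Usage: python admixsim.py <config.json>
"""

import collections
import json
import os
import sys

import msprime
import numpy as np

POP_ADM, POP_CON, POP_ANC = 0, 1, 2
POP_NAMES = {POP_ADM: "ADM", POP_CON: "CON", POP_ANC: "ANC"}


def build_demography(p):
    alpha = p["alpha"]
    g = p["adm_start_gen"] - p["adm_end_gen"]
    m = 1.0 - alpha ** (1.0 / g)
    dem = msprime.Demography()
    dem.add_population(name="ADM", initial_size=p["ne"])
    dem.add_population(name="CON", initial_size=p["ne"])
    dem.add_population(name="ANC", initial_size=p["ne"])
    if m > 0:
        dem.add_migration_rate_change(
            time=p["adm_end_gen"], rate=m, source="ADM", dest="CON")
        dem.add_migration_rate_change(
            time=p["adm_start_gen"], rate=0, source="ADM", dest="CON")
    census_t = p["adm_start_gen"] + 1.0
    dem.add_census(time=census_t)
    dem.add_population_split(
        time=p["split_gen"], derived=["ADM", "CON"], ancestral="ANC")
    dem.sort_events()
    return dem, m, census_t


def mutation_origin(ts, node_migs, node_pops, site_pos, node, time):
    """Population carrying the lineage of `node` at `time` for `site_pos`."""
    pop = node_pops[node]
    for (mt, left, right, dest) in node_migs.get(node, ()):
        if mt <= time and left <= site_pos < right:
            pop = dest
    return pop


def run_replicate(p, seed, out_dir):
    dem, m, census_t = build_demography(p)
    n_ind = p["n_hap_per_group"] // 2
    samples = [
        msprime.SampleSet(n_ind, population="ADM", time=0),
        msprime.SampleSet(n_ind, population="CON", time=0),
        msprime.SampleSet(n_ind, population="ADM", time=p["adm_start_gen"]),
        msprime.SampleSet(n_ind, population="CON", time=p["adm_start_gen"]),
    ]
    ts = msprime.sim_ancestry(
        samples=samples, demography=dem,
        sequence_length=p["seq_len_bp"],
        recombination_rate=p["rho"],
        record_migrations=True, random_seed=seed)
    ts = msprime.sim_mutations(ts, rate=p["mu"], random_seed=seed)

    node_pops = ts.tables.nodes.population
    mig = ts.tables.migrations
    node_migs = collections.defaultdict(list)
    for i in range(len(mig)):
        node_migs[mig.node[i]].append(
            (mig.time[i], mig.left[i], mig.right[i], mig.dest[i]))
    for v in node_migs.values():
        v.sort()

    # --- ancestry tracts of the modern admixed haplotypes -------------------
    census_nodes = np.where(ts.tables.nodes.time == census_t)[0].astype(np.int32)
    adm_haps = np.arange(p["n_hap_per_group"], dtype=np.int32)
    anc = ts.tables.link_ancestors(samples=adm_haps, ancestors=census_nodes)
    seq_len = int(p["seq_len_bp"])
    tract_rows = []
    by_child = collections.defaultdict(list)
    for i in range(len(anc)):
        src = 1 if node_pops[anc.parent[i]] == POP_ADM else 2
        by_child[anc.child[i]].append((anc.left[i], anc.right[i], src))
    for hap in range(p["n_hap_per_group"]):
        segs = sorted(by_child.get(hap, [(0.0, float(seq_len), 1)]))
        merged = []
        for left, right, src in segs:
            if merged and merged[-1][2] == src and merged[-1][1] == left:
                merged[-1][1] = right
            else:
                merged.append([left, right, src])
        for left, right, src in merged:
            tract_rows.append((hap, int(left), int(right), src))

    # --- site table ---------------------------------------------------------
    geno = ts.genotype_matrix()  # sites x haplotypes
    os.makedirs(out_dir, exist_ok=True)
    with open(os.path.join(out_dir, "sites.tsv"), "w") as fh:
        fh.write("pos\torigin_pop\torigin_time\thaps\n")
        for site in ts.sites():
            if len(site.mutations) != 1:
                continue
            mut = site.mutations[0]
            pop = mutation_origin(ts, node_migs, node_pops,
                                  site.position, mut.node, mut.time)
            row = geno[site.id]
            if row.max() > 1:  # defensive: never true for single-mutation sites
                continue
            fh.write("%d\t%s\t%.6f\t%s\n" % (
                int(site.position) + 1, POP_NAMES[pop], mut.time,
                "".join("1" if x else "0" for x in row)))
    with open(os.path.join(out_dir, "tracts.tsv"), "w") as fh:
        fh.write("hap\tstart\tend\tsource\n")
        for row in tract_rows:
            fh.write("%d\t%d\t%d\t%d\n" % row)
    meta = dict(p)
    meta.update(seed=seed, migration_rate=m,
                groups=["admixed", "source2_modern",
                        "source1_ancient", "source2_ancient"])
    with open(os.path.join(out_dir, "meta.json"), "w") as fh:
        json.dump(meta, fh, indent=1)


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    p = cfg["model"]
    for seed in cfg["seeds"]:
        run_replicate(p, int(seed),
                      os.path.join(cfg["out_dir"], "rep_%d" % int(seed)))


if __name__ == "__main__":
    main()
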