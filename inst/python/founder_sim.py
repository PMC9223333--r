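#!/usr/bin/env python
"""Coalescent simulation backend for the ascendr package.

Usage: founder_sim.py config.json out_prefix

Simulates a two-population founder-event demography (or a three-population
admixture variant) with msprime and writes haploid genotypes as an
EIGENSTRAT-style triplet (<prefix>.geno/.snp/.ind, alleles coded 0/1, one
column per haploid genome) plus a small JSON manifest. All demographic
parameters come from the JSON config written by the R side; this script owns
no defaults.
"""
import json
import sys

import msprime
import numpy as np


def build_demography(cfg):
    dem = msprime.Demography()
    N_o = cfg["N_o"]
    model = cfg.get("model", "founder")
    has_bottleneck = cfg.get("N_f") is not None
    if model == "founder":
        dem.add_population(name="A", initial_size=N_o)
        dem.add_population(name="O", initial_size=N_o)
        dem.add_population(name="ANC", initial_size=N_o)
        if has_bottleneck:
            dem.add_population_parameters_change(
                time=cfg["T_f"], population="A", initial_size=cfg["N_f"])
            dem.add_population_parameters_change(
                time=cfg["T_f"] + cfg["D_f"], population="A", initial_size=N_o)
        dem.add_population_split(time=cfg["divergence_time"],
                                 derived=["A", "O"], ancestral="ANC")
        samples = {"A": cfg["haploids_per_pop"] // 2,
                   "O": cfg["haploids_per_pop"] // 2}
    elif model == "admixture":
        adm = cfg["admixture"]
        dem.add_population(name="A", initial_size=N_o)
        dem.add_population(name="O", initial_size=N_o)   # outgroup = source 1
        dem.add_population(name="B", initial_size=N_o)   # source 2
        dem.add_population(name="ANC", initial_size=N_o)
        if has_bottleneck:
            dem.add_population_parameters_change(
                time=cfg["T_f"], population="A", initial_size=cfg["N_f"])
            dem.add_population_parameters_change(
                time=cfg["T_f"] + cfg["D_f"], population="A", initial_size=N_o)
        dem.add_admixture(time=adm["time"], derived="A", ancestral=["O", "B"],
                          proportions=list(adm["proportions"]))
        dem.add_population_split(time=cfg["divergence_time"],
                                 derived=["O", "B"], ancestral="ANC")
        samples = {"A": cfg["haploids_per_pop"] // 2,
                   "O": cfg["haploids_per_pop"] // 2}
    else:
        raise ValueError("unknown model: %s" % model)
    dem.sort_events()
    return dem, samples


def main():
    cfg_path, prefix = sys.argv[1], sys.argv[2]
    with open(cfg_path) as fh:
        cfg = json.load(fh)

    dem, samples = build_demography(cfg)
    n_chrom = int(cfg["n_chromosomes"])
    L = float(cfg["chromosome_length_bp"])
    rec = float(cfg["recombination_rate"])
    mut = float(cfg["mutation_rate"])

    ss = np.random.SeedSequence(int(cfg["seed"]))
    seeds = (ss.generate_state(2 * n_chrom, dtype=np.uint32).astype(np.int64)
             % (2**31 - 2)) + 1

    n_hap = 2 * (cfg["haploids_per_pop"] // 2) * 2  # haploid genomes, both pops
    geno_fh = open(prefix + ".geno", "wb")
    snp_fh = open(prefix + ".snp", "w")
    n_sites_total = 0
    for c in range(n_chrom):
        ts = msprime.sim_ancestry(
            samples=samples, demography=dem, ploidy=2,
            sequence_length=L, recombination_rate=rec,
            discrete_genome=False, random_seed=int(seeds[2 * c]))
        ts = msprime.sim_mutations(ts, rate=mut, discrete_genome=False,
                                   random_seed=int(seeds[2 * c + 1]))
        G = ts.genotype_matrix().astype(np.uint8)
        if G.shape[0] == 0:
            continue
        G = np.minimum(G, 1)  # guard: binary coding
        block = np.empty((G.shape[0], n_hap + 1), dtype=np.uint8)
        block[:, :n_hap] = G + ord("0")
        block[:, n_hap] = ord("\n")
        geno_fh.write(block.tobytes())
        pos = ts.tables.sites.position
        chrom = str(c + 1)
        for i, p in enumerate(pos):
            gpos = p * rec  # constant-rate map, Morgans
            snp_fh.write("snp_%s_%d\t%s\t%.17g\t%d\tA\tG\n"
                         % (chrom, i + 1, chrom, gpos, int(p) + 1))
        n_sites_total += G.shape[0]
    geno_fh.close()
    snp_fh.close()

    k = cfg["haploids_per_pop"] // 2 * 2
    with open(prefix + ".ind", "w") as fh:
        for pop in ("A", "O"):
            for i in range(k):
                fh.write("%s_h%d\tU\t%s\n" % (pop, i + 1, pop))

    nominal_If = None
    if cfg.get("N_f") is not None:
        nominal_If = cfg["D_f"] / (2.0 * cfg["N_f"])
    with open(prefix + ".manifest.json", "w") as fh:
        json.dump({"engine": "msprime", "engine_version": msprime.__version__,
                   "seed": cfg["seed"], "model": cfg.get("model", "founder"),
                   "n_sites": n_sites_total,
                   "nominal_T_f": cfg.get("T_f"), "nominal_I_f": nominal_If},
                  fh, indent=1)


if __name__ == "__main__":
    main()
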