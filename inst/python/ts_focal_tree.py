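"""Extract the marginal tree (newick, branch lengths in generations) and the
derived-carrier set at a focal position from a tskit tree sequence.

Usage: python ts_focal_tree.py <file.trees> <focal_position>
Prints a JSON object {"newick": ..., "derived": [tip labels], "interval": [a, b]}.
"""
import json
import sys

import tskit


def main() -> None:
    path, pos = sys.argv[1], float(sys.argv[2])
    ts = tskit.load(path)
    if not (0 <= pos < ts.sequence_length):
        raise SystemExit("range error: focal position outside the sequence")
    tree = ts.at(pos)
    labels = {u: f"n{u}" for u in ts.samples()}
    newick = tree.as_newick(node_labels=labels)
    derived = []
    best = None
    for var in ts.variants():
        if len(var.alleles) != 2:
            continue
        d = abs(var.site.position - pos)
        if best is None or d < best[0]:
            best = (d, var)
    if best is not None and best[0] < 0.5:
        var = best[1]
        derived = [labels[u] for u, g in zip(ts.samples(), var.genotypes) if g == 1]
    print(json.dumps({
        "newick": newick,
        "derived": derived,
        "interval": list(tree.interval),
    }))


if __name__ == "__main__":
    main()
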