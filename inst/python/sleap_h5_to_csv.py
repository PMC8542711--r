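"""Convert a pose-tracking HDF5 analysis export to the long CSV layout.

Expected datasets (the analysis export of the SLEAP-style tracker):
  tracks       float (n_tracks, 2, n_nodes, n_frames); NaN = undetected
  node_names   bytes (n_nodes,)
  track_names  bytes (n_tracks,)  [optional; track_0.. otherwise]

Usage: python sleap_h5_to_csv.py in.h5 out.csv
"""
import csv
import sys

import h5py
import numpy as np


def main(h5_path, csv_path):
    with h5py.File(h5_path, "r") as f:
        tracks = np.asarray(f["tracks"])            # (T, 2, N, F)
        nodes = [n.decode() if isinstance(n, bytes) else str(n)
                 for n in f["node_names"][:]]
        if "track_names" in f:
            names = [n.decode() if isinstance(n, bytes) else str(n)
                     for n in f["track_names"][:]]
        else:
            names = [f"track_{i}" for i in range(tracks.shape[0])]
    n_tracks, _, n_nodes, n_frames = tracks.shape
    with open(csv_path, "w", newline="") as out:
        w = csv.writer(out)
        w.writerow(["frame", "track", "node", "x", "y"])
        for fr in range(n_frames):
            for ti in range(n_tracks):
                for ni in range(n_nodes):
                    x, y = tracks[ti, 0, ni, fr], tracks[ti, 1, ni, fr]
                    w.writerow([fr + 1, names[ti], nodes[ni],
                                "" if np.isnan(x) else repr(float(x)),
                                "" if np.isnan(y) else repr(float(y))])


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
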