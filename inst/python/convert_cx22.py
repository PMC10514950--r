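"""Convert a Cx22-style MATLAB v7.3 (.mat / HDF5) container to PNG triplets.

Usage: python convert_cx22.py <container> <out_dir> [<keys_json>]

keys_json, if given, is a JSON object {"image": ..., "cyto": ..., "nuc": ...}
naming the HDF5 datasets explicitly.  Without it, datasets are
auto-discovered by shape: the array with a channel axis of size 3 is the
image stack; of the two remaining mask stacks the one with the larger
foreground area is taken as cytoplasm (nuclei are a small minority class).

Two layouts are supported: stacked top-level datasets (sample axis first),
and one HDF5 group per sample each holding an image and two masks.
MATLAB's transposed storage order is detected per array and undone.

Writes <id>.png, <id>_cyto.png, <id>_nuc.png per sample and prints the
number of samples written on the last stdout line.
"""
import json
import os
import sys

import h5py
import numpy as np
from PIL import Image


def fail(msg):
    sys.stderr.write(msg + "\n")
    sys.exit(1)


def to_uint8(arr):
    arr = np.asarray(arr)
    if arr.dtype == np.uint8:
        return arr
    mx = arr.max() if arr.size else 1.0
    if mx <= 1.0:
        return (arr * 255).round().astype(np.uint8)
    return np.clip(arr, 0, 255).round().astype(np.uint8)


def orient_image(a):
    """Return one image as (H, W, 3) uint8."""
    a = np.asarray(a)
    if a.ndim != 3:
        fail("image array must have 3 axes per sample, got %d" % a.ndim)
    ch = [i for i, s in enumerate(a.shape) if s == 3]
    if not ch:
        fail("no channel axis of size 3 in image array")
    a = np.moveaxis(a, ch[0], -1)
    if a.shape[0] < a.shape[1] and a.shape[1] != a.shape[0]:
        pass  # non-square images are passed through as stored
    return to_uint8(a)


def orient_mask(a, like_hw):
    a = np.asarray(a)
    if a.ndim != 2:
        fail("mask array must have 2 axes per sample, got %d" % a.ndim)
    if a.shape != like_hw and a.shape[::-1] == like_hw:
        a = a.T  # MATLAB transposed storage
    if a.shape != like_hw:
        fail("mask shape %s does not match image %s" % (a.shape, like_hw))
    u8 = to_uint8(a)
    return ((u8 > 127) * 255).astype(np.uint8)


def write_sample(out_dir, sid, img, cyto, nuc):
    Image.fromarray(img).save(os.path.join(out_dir, sid + ".png"))
    Image.fromarray(cyto).save(os.path.join(out_dir, sid + "_cyto.png"))
    Image.fromarray(nuc).save(os.path.join(out_dir, sid + "_nuc.png"))


def classify_masks(masks):
    """masks: list of (name, array). Return (cyto, nuc) arrays."""
    named = {}
    for name, arr in masks:
        low = name.lower()
        if "cyto" in low or low.endswith("cy"):
            named["cyto"] = arr
        elif "nuc" in low or "kern" in low:
            named["nuc"] = arr
    if "cyto" in named and "nuc" in named:
        return named["cyto"], named["nuc"]
    if len(masks) != 2:
        return None
    a0, a1 = masks[0][1], masks[1][1]
    m0 = float(np.asarray(a0, dtype=np.float64).mean())
    m1 = float(np.asarray(a1, dtype=np.float64).mean())
    return (a0, a1) if m0 >= m1 else (a1, a0)


def main():
    if len(sys.argv) < 3:
        fail("usage: convert_cx22.py <container> <out_dir> [<keys_json>]")
    container, out_dir = sys.argv[1], sys.argv[2]
    keys = json.loads(sys.argv[3]) if len(sys.argv) > 3 else None
    os.makedirs(out_dir, exist_ok=True)
    count = 0

    with h5py.File(container, "r") as f:
        groups = [k for k in f.keys()
                  if isinstance(f[k], h5py.Group) and not k.startswith("#")]
        dsets = [k for k in f.keys() if isinstance(f[k], h5py.Dataset)]

        if groups and not keys:
            for gname in sorted(groups):
                g = f[gname]
                imgs, masks = [], []
                for k in g.keys():
                    arr = g[k][()]
                    if arr.ndim == 3 and 3 in arr.shape:
                        imgs.append((k, arr))
                    elif arr.ndim == 2:
                        masks.append((k, arr))
                if not imgs:
                    fail("sample '%s': no image array found" % gname)
                pair = classify_masks(masks)
                if pair is None:
                    fail("sample '%s': missing cytoplasm or nucleus mask"
                         % gname)
                img = orient_image(imgs[0][1])
                hw = img.shape[:2]
                cyto = orient_mask(pair[0], hw)
                nuc = orient_mask(pair[1], hw)
                write_sample(out_dir, gname, img, cyto, nuc)
                count += 1
        else:
            if keys:
                img_key = keys["image"]
                mask_items = [(keys["cyto"], f[keys["cyto"]][()]),
                              (keys["nuc"], f[keys["nuc"]][()])]
                img_arr = f[img_key][()]
                cyto_arr, nuc_arr = mask_items[0][1], mask_items[1][1]
            else:
                if not dsets and not groups:
                    print(0)
                    return
                cand = [(k, f[k][()]) for k in dsets]
                # the image stack has the highest rank (4D stacked, or 3D
                # for a single sample) and carries a channel axis of 3;
                # a sample count of 3 can mimic a channel axis in mask
                # stacks, so rank is decided first
                maxd = max(a.ndim for _, a in cand)
                imgs = [(k, a) for k, a in cand
                        if a.ndim == maxd and a.ndim >= 3 and 3 in a.shape]
                if len(imgs) != 1:
                    fail("cannot identify the image dataset by shape; "
                         "use an explicit key mapping")
                img_key, img_arr = imgs[0]
                mask_items = [(k, a) for k, a in cand
                              if k != img_key and a.ndim in (2, 3)
                              and a.ndim < img_arr.ndim]
                pair = classify_masks(mask_items)
                if pair is None:
                    fail("sample 'sample_00001': missing cytoplasm or "
                         "nucleus mask array")
                cyto_arr, nuc_arr = pair

            if img_arr.ndim == 3:  # single sample
                img_arr = img_arr[None]
                cyto_arr = np.asarray(cyto_arr)[None]
                nuc_arr = np.asarray(nuc_arr)[None]
            n = img_arr.shape[0]
            for key, arr in (("cyto", cyto_arr), ("nuc", nuc_arr)):
                if np.asarray(arr).shape[0] != n:
                    fail("mask stack '%s' has %d samples, image stack has %d"
                         % (key, np.asarray(arr).shape[0], n))
            for i in range(n):
                sid = "sample_%05d" % (i + 1)
                img = orient_image(img_arr[i])
                hw = img.shape[:2]
                cyto = orient_mask(np.asarray(cyto_arr)[i], hw)
                nuc = orient_mask(np.asarray(nuc_arr)[i], hw)
                write_sample(out_dir, sid, img, cyto, nuc)
                count += 1

    print(count)


if __name__ == "__main__":
    main()
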