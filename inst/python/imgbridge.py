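"""Decode PNG/JPEG/DICOM frames to plain PGM and encode PGM back to PNG.

Called by the R package through system2(); keeps all binary-format handling
in one place so the R side only ever parses PGM.
"""
import sys


def write_pgm(arr, path, maxval):
    h, w = arr.shape
    with open(path, "w") as fh:
        fh.write("P2\n%d %d\n%d\n" % (w, h, maxval))
        for row in arr:
            fh.write(" ".join(str(int(v)) for v in row) + "\n")


def read_pgm(path):
    with open(path) as fh:
        tok = fh.read().split()
    assert tok[0] == "P2"
    w, h, mx = int(tok[1]), int(tok[2]), int(tok[3])
    import numpy as np
    vals = np.array(tok[4:4 + w * h], dtype=np.int64)
    return vals.reshape(h, w), mx


def decode(src, dst, collapse):
    import numpy as np
    from PIL import Image
    img = Image.open(src)
    arr = np.asarray(img)
    deep = arr.dtype.itemsize > 1          # per-channel bit depth > 8
    if arr.ndim == 3:
        ch = arr[..., :3].astype(np.int64)
        equal = (ch[..., 0] == ch[..., 1]).all() and (ch[..., 0] == ch[..., 2]).all()
        if equal:
            arr = ch[..., 0]
        elif collapse:
            arr = np.rint(ch.mean(axis=2)).astype(np.int64)
        else:
            sys.exit("multi-channel image with unequal channels; "
                     "use collapse flag")
    maxval = 65535 if deep or int(arr.max()) > 255 else 255
    write_pgm(arr.astype(np.int64), dst, maxval)


def dicom(src, dst, collapse):
    import numpy as np
    import pydicom
    ds = pydicom.dcmread(src)
    if getattr(ds, "Modality", None) != "US":
        sys.exit("DICOM modality is not US")
    arr = ds.pixel_array
    deep = arr.dtype.itemsize > 1
    if arr.ndim == 3:
        ch = arr[..., :3].astype(np.int64)
        if (ch[..., 0] == ch[..., 1]).all() and (ch[..., 0] == ch[..., 2]).all():
            arr = ch[..., 0]
        elif collapse:
            arr = np.rint(ch.mean(axis=2)).astype(np.int64)
        else:
            sys.exit("multi-channel DICOM with unequal channels; "
                     "use collapse flag")
    maxval = 65535 if deep or int(arr.max()) > 255 else 255
    write_pgm(arr.astype(np.int64), dst, maxval)


def encode(src, dst):
    import numpy as np
    from PIL import Image
    arr, _ = read_pgm(src)
    Image.fromarray(arr.astype(np.uint8), mode="L").save(dst)


def main(argv):
    mode, src, dst = argv[0], argv[1], argv[2]
    collapse = "--collapse" in argv[3:]
    if mode == "decode":
        decode(src, dst, collapse)
    elif mode == "dicom":
        dicom(src, dst, collapse)
    elif mode == "encode":
        encode(src, dst)
    else:
        sys.exit("unknown mode: " + mode)


if __name__ == "__main__":
    main(sys.argv[1:])
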