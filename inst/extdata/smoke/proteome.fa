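>g001.t1
MPSQIGTRSRFSALKWGVTEKTSGLAAMRPVRLLHSFMNPGGALSAYP
>g001.t2
MPSQIGTRSRFSALKWGVTEKTSGLAAMRPVRLLHSFMNPGGALSAYP
>g001.t3
MPSQIGTRSRFSALKWGVTEKTSGLAAMRPVRLLHSFMNPGGALSAYP
>g001.tg
MPSQIGTRSRFSALKWGVTEKTSGLAAMRPVRLLHSFMNPGGALSAYP
>g002.t1
MRRLVKSGPKVSLILVSTGRLRYILGLLDGGGDPPPCTVADGSRDPVRIESCWTA
>g002.t2
MKRVAIIWKSPPAVHAQATSTGRASNSLMNTNPPYRSREEQTSAWSRKC
>g002.t3
MRRLVKSGPKVSLILVSTGRLRYILGLLDGGGDPPPCTVADGSRIRPIDHERNRPQHGVGSVDLRYTKPCDSAKSP
>g003.t1
MRFYVIPDSMLFDALGAPLLSWASDQIYSDMTSIPTFSPRWITVTCLWLVRWCNPKGHQR
>g003.t2
MVQPQRSSALESSGRYLTLRVASCKSFLHGCKRSCRRPS
>g003.t3
MRFYVIPDSMLFDALGAPLLSWASDQIYSDYVWQAARAFYTGASEVAGDRPRHRPHKLRGA
>g004.t1
MRTYHNSHRRPRTERCLFSFSFSLRSQRQMSPTRPWLRVQAWPLTP
>g004.t2
MRTYHNSHRRPRTERFGKPIAAPRQTLTGKGN
>g004.t3
MRTYHNSHRRPRTERCLFSFSFSLRSQRQMSPTRPWLRVQAWPLTP
>g006.t1
MRLSESMELFRVSMEESHYAILSARFEVGSKLVLLYHLWSMADLCVARPRTVHHTRLDNQHR
>g006.t2
MTEGKDTLNAATPRRPHNSGGSARRRDRRTSTYAERQVPSR
>g006.t3
MRLSESMELFRVSMEESHYAILSARFEVGSKLVLLYHLWSMADLCVARPRTVHHTRLDNQHR
>g006.tn
MTEGKDTLNAATPRRPHNSGGSARRRDRRTSTYAERQVPSR
>g002.tx
MRRLVKSGPKVSLILVSTGRLRYILGLLDGGGDPPPCTVADGSRDPVRIESCWTA
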