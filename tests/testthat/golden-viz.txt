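<!DOCTYPE html>
<html><head><meta charset="utf-8"/>
<title>Attention heatmap report</title>
<style>
body{font-family:sans-serif;max-width:60em;margin:1em auto;}
.doc{margin-bottom:2em;border-top:1px solid #ccc;padding-top:1em;}
.sent{display:block;margin:0.15em 0;padding-left:0.6em;}
.tok{padding:0.05em 0.15em;border-radius:0.15em;}
.lex{text-decoration:underline;}
.mass{color:#555;font-size:smaller;}
</style></head><body>
<h1>Attention heatmap report</h1>
<p>Green background: hierarchically normalized word weight; red left bar: sentence weight. Opacities are rescaled by each document's maximum weight so short documents stay readable. Underlined tokens belong to a marker lexicon.</p>
<div class="doc">
<h2>d</h2>
<p class="mass">predicted: AD; true: AD</p>
<span class="sent" style="border-left:0.5em solid rgba(200,0,0,1.000000)"><span class="tok" style="background:rgba(0,160,0,0.285714)">the</span> <span class="tok lex" style="background:rgba(0,160,0,1.000000)">boy</span> <span class="tok" style="background:rgba(0,160,0,0.142857)">.</span></span>
<span class="sent" style="border-left:0.5em solid rgba(200,0,0,0.250000)"><span class="tok lex" style="background:rgba(0,160,0,0.321429)">uh</span> <span class="tok" style="background:rgba(0,160,0,0.035714)">.</span></span>
<p class="mass">attention mass on lexicons: seed_words 0.560000; fillers 0.180000; pronouns 0.000000</p>
</div>
</body></html>
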