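a
an
the
and
or
but
of
in
on
at
to
for
with
by
from
as
is
are
was
were
be
been
being
it
its
this
that
these
those
which
who
whom
what
when
where
how
not
no
nor
so
than
then
there
here
we
our
can
could
may
might
will
would
causes
using
based
study
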